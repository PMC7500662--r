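# shared helpers for the pedkit test suite

# unique scratch paths under one per-session root (cleaned up with the
# session tempdir); a counter keeps the RNG stream untouched
.tmp_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

tmp_path <- function(...) {
  d <- file.path(tempdir(), "pedkit-tests", sprintf("t%06d", .tmp_counter()))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  parts <- c(...)
  if (!length(parts) || identical(parts, "")) return(d)
  file.path(d, ...)
}

# a tiny deterministic dataset with known columns
toy_dataset <- function() {
  ped_dataset(
    samples = tibble::tibble(
      family_id = paste0("F", 1:4), individual_id = paste0("I", 1:4),
      paternal_id = "0", maternal_id = "0",
      sex = c("1", "2", "1", "2"), phenotype = c("2", "1", "2", "1")),
    snps = tibble::tibble(chrom = "1", snp_id = paste0("rs", 1:3),
                          cm = 0, bp = c(100, 200, 300)),
    genotypes = matrix(c("AA", "AC", "CC", "00",
                         "GG", "GT", "GG", "TT",
                         "CC", "CC", "CC", "CC"), nrow = 4))
}

# independent BED decoder sharing no code with the package reader: walks
# the payload byte by byte with bitwAnd/bitwShiftR and rebuilds the calls
oracle_read_bed <- function(bed, bim, fam) {
  fam_rows <- read.table(fam, colClasses = "character")
  bim_rows <- read.table(bim, colClasses = "character")
  n <- nrow(fam_rows); m <- nrow(bim_rows)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  stopifnot(raw[1] == as.raw(0x6C), raw[2] == as.raw(0x1B),
            raw[3] == as.raw(0x01))
  payload <- as.integer(raw[-(1:3)])
  bpp <- ceiling(n / 4)
  geno <- matrix("", n, m)
  for (j in seq_len(m)) {
    a1 <- bim_rows[j, 5]; a2 <- bim_rows[j, 6]
    block <- payload[(j - 1) * bpp + seq_len(bpp)]
    for (i in seq_len(n)) {
      byte <- block[((i - 1) %/% 4) + 1]
      code <- bitwAnd(bitwShiftR(byte, 2 * ((i - 1) %% 4)), 3L)
      geno[i, j] <- switch(code + 1L,
                           paste0(a1, a1), "00", paste0(a1, a2),
                           paste0(a2, a2))
    }
  }
  geno
}

# unordered-pair grid equality (local reimplementation for tests)
grids_equal <- function(a, b) {
  norm <- function(g) {
    x1 <- substr(g, 1, 1); x2 <- substr(g, 2, 2)
    x1[x1 == "N"] <- "0"; x2[x2 == "N"] <- "0"
    swap <- utf8ToInt("z")  # force code-point comparison per cell
    m <- mapply(function(p, q) paste(sort(c(p, q), method = "radix"),
                                     collapse = ""), x1, x2)
    matrix(m, nrow(g), ncol(g))
  }
  identical(dim(a), dim(b)) && all(norm(a) == norm(b))
}

# random arguments-file text + matching output path count, for round-trip
# properties across orientations, cell layouts and 1-2 output files
random_user_spec <- function() {
  orientation <- sample(c("samples-as-rows", "snps-as-rows"), 1)
  cell <- sample(c("split", "fused"), 1)
  two_files <- runif(1) < 0.4
  lines <- c("MATRIX", "file, 1",
             paste0("orientation, ", orientation),
             paste0("cell, ", cell),
             "delimiter, space")
  vec <- "VECTOR"
  ins <- "INSERT"
  if (orientation == "samples-as-rows") {
    vec <- c(vec, "IndividualID, 1", "Phenotype, 2")
    if (two_files) {
      lines <- c(lines, "delimiter, tab, 2")
      vec <- c(vec, "SNPID, 1, 2")
    } else {
      vec <- c(vec, "SNPID, 1")  # marker-id row
      ins <- c(ins, "row, 2, #")  # allele/SNP serial header below it
    }
  } else {
    vec <- c(vec, "SNPID, 1", "IndividualID, 1")
    ins <- c(ins, "col, 2, \\$")  # literal constant column
  }
  list(text = c(lines, vec, ins),
       n_files = if (two_files && orientation == "samples-as-rows") 2L else 1L)
}
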