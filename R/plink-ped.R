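#' Read a PLINK PED/MAP fileset
#'
#' Each PED row holds the six pedigree columns followed by two allele
#' tokens per SNP.  Sample order follows row order and SNP order follows
#' the MAP; a PED may be read without a MAP, in which case placeholder
#' marker records (`chrom 0`, ids `snp_1..m`, positions 0) are generated.
#' Multi-character allele tokens are reduced to their first character with
#' a warning; half-missing calls become fully missing with a warning.
#'
#' @param ped Path to the .ped file.
#' @param map Optional path to the .map file (4 columns: chromosome,
#'   marker id, genetic distance, bp position).
#' @return A [ped_dataset()].
#' @export
read_ped <- function(ped, map = NULL) {
  lines <- read_text_lines(ped)
  fields <- ws_split(lines)
  fields <- fields[lengths(fields) > 0L]
  if (!length(fields)) {
    return(empty_dataset(read_map_records(map, 0L)))
  }
  width <- lengths(fields)
  if (any(width != width[[1L]])) {
    bad <- which(width != width[[1L]])[[1L]]
    abort(sprintf("PED row %d has %d fields but row 1 has %d",
                  bad, width[[bad]], width[[1L]]),
          class = "pedkit_parse_error")
  }
  if (width[[1L]] < 6L) {
    abort(sprintf("PED row 1 has only %d fields; 6 pedigree columns required",
                  width[[1L]]),
          class = "pedkit_parse_error")
  }
  n_allele_fields <- width[[1L]] - 6L
  if (n_allele_fields %% 2L != 0L) {
    abort(sprintf(
      "PED row 1 has an odd number of allele fields (%d) after 6 pedigree columns",
      n_allele_fields), class = "pedkit_parse_error")
  }
  m <- n_allele_fields %/% 2L
  mat <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  samples <- tibble(family_id = mat[, 1L], individual_id = mat[, 2L],
                    paternal_id = mat[, 3L], maternal_id = mat[, 4L],
                    sex = mat[, 5L], phenotype = mat[, 6L])
  snps <- read_map_records(map, m)
  if (nrow(snps) != m) {
    abort(sprintf("MAP lists %d SNP(s) but PED carries %d", nrow(snps), m),
          class = "pedkit_structure_error")
  }
  geno <- alleles_to_calls(mat[, -(1:6), drop = FALSE])
  ped_dataset(samples, snps, geno)
}

# interleaved allele token matrix (n x 2m) -> call matrix (n x m),
# reducing multi-character tokens with a single warning
alleles_to_calls <- function(allele_mat) {
  m <- ncol(allele_mat) %/% 2L
  if (length(allele_mat) && any(nchar(allele_mat) != 1L)) {
    warn(sprintf("%d multi-character allele token(s) reduced to first character",
                 sum(nchar(allele_mat) != 1L)))
    allele_mat[] <- reduce_allele(allele_mat)
  }
  a1 <- allele_mat[, 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- allele_mat[, 2L * seq_len(m), drop = FALSE]
  geno <- paste0(a1, a2)
  dim(geno) <- c(nrow(allele_mat), m)
  geno
}

read_map_records <- function(map, m_fallback) {
  if (is.null(map)) {
    return(tibble(chrom = rep("0", m_fallback),
                  snp_id = if (m_fallback) paste0("snp_", seq_len(m_fallback))
                           else character(),
                  cm = rep(0, m_fallback), bp = rep(0, m_fallback)))
  }
  fields <- ws_split(read_text_lines(map))
  fields <- fields[lengths(fields) > 0L]
  if (!length(fields)) {
    return(tibble(chrom = character(), snp_id = character(),
                  cm = numeric(), bp = numeric()))
  }
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    abort(sprintf("MAP row %d has %d fields; expected 4 (chrom id cM bp)",
                  bad[[1L]], length(fields[[bad[[1L]]]])),
          class = "pedkit_parse_error")
  }
  mat <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  tibble(chrom = mat[, 1L], snp_id = mat[, 2L],
         cm = as.numeric(mat[, 3L]), bp = as.numeric(mat[, 4L]))
}

empty_dataset <- function(snps) {
  ped_dataset(
    tibble(family_id = character(), individual_id = character(),
           paternal_id = character(), maternal_id = character(),
           sex = character(), phenotype = character()),
    snps, matrix(character(), 0L, nrow(snps)))
}

#' Write a PLINK PED/MAP fileset
#'
#' One sample per line with a single-space delimiter, newline-terminated;
#' the MAP carries the four marker columns (chromosome, id, genetic
#' distance, bp).
#'
#' @param ds A [ped_dataset()].
#' @param ped Output .ped path.
#' @param map Optional output .map path (omit to skip writing the MAP).
#' @return Invisibly, the .ped path.
#' @export
write_ped <- function(ds, ped, map = NULL) {
  lines <- ped_lines(ds)
  write_text_lines(lines, ped)
  if (!is.null(map)) write_map(ds$snps, map)
  invisible(ped)
}

ped_lines <- function(ds) {
  n <- n_samples(ds); m <- n_snps(ds)
  left <- paste(ds$samples$family_id, ds$samples$individual_id,
                ds$samples$paternal_id, ds$samples$maternal_id,
                ds$samples$sex, ds$samples$phenotype)
  if (m == 0L || n == 0L) return(left)
  allele_mat <- matrix("", n, 2L * m)
  allele_mat[, 2L * seq_len(m) - 1L] <- substr(ds$genotypes, 1L, 1L)
  allele_mat[, 2L * seq_len(m)] <- substr(ds$genotypes, 2L, 2L)
  paste(left, paste_rows(allele_mat))
}

write_map <- function(snps, map) {
  write_text_lines(paste(snps$chrom, snps$snp_id,
                         format_num(snps$cm), format_num(snps$bp)),
                   map)
}

# positions/distances printed without scientific notation or trailing .0
format_num <- function(x) {
  out <- format(x, scientific = FALSE, trim = TRUE)
  sub("\\.0+$", "", out)
}
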