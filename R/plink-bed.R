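#' Write a PLINK binary BED/BIM/FAM fileset
#'
#' Writes the SNP-major v1.00 binary layout: magic bytes `0x6C 0x1B`, mode
#' byte `0x01`, then for each SNP a block of `ceiling(n_samples / 4)`
#' bytes.  Each byte packs four genotypes, two bits each, lowest bits
#' first: `00` = homozygous allele-1, `01` = missing, `10` = heterozygous,
#' `11` = homozygous allele-2.  Allele-1 is the minor and allele-2 the
#' major allele (recorded in BIM columns 5-6), ties resolved by the ASCII
#' rule of [allele_summary()].  Padding bits of the last byte in each
#' block are zero.
#'
#' @param ds A [ped_dataset()]; every SNP must be at most biallelic.
#' @param bed,bim,fam Output paths.
#' @return Invisibly, the .bed path.
#' @export
write_bed <- function(ds, bed, bim, fam) {
  n <- n_samples(ds); m <- n_snps(ds)
  summ <- allele_summary(ds)
  # per-call 2-bit codes, SNP-major
  codes <- matrix(0L, n, m)
  if (n && m) {
    a1 <- substr(ds$genotypes, 1L, 1L); dim(a1) <- c(n, m)
    a2 <- substr(ds$genotypes, 2L, 2L); dim(a2) <- c(n, m)
    miss <- is_missing_char(a1) | is_missing_char(a2)
    maj <- matrix(rep(summ$major, each = n), n, m)
    het <- !miss & a1 != a2
    hom_major <- !miss & !het & a1 == maj
    hom_minor <- !miss & !het & a1 != maj
    codes[miss] <- 1L
    codes[het] <- 2L
    codes[hom_major] <- 3L
    # hom_minor stays 0
  }
  n4 <- 4L * ceiling(n / 4L)
  padded <- matrix(0L, n4, m)
  if (n && m) padded[seq_len(n), ] <- codes
  dim(padded) <- c(4L, (n4 %/% 4L) * m)
  bytes <- padded[1L, ] + 4L * padded[2L, ] + 16L * padded[3L, ] +
    64L * padded[4L, ]
  con <- file(bed, open = "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  if (length(bytes)) writeBin(as.raw(bytes), con)

  minor_out <- summ$minor
  write_text_lines(paste(ds$snps$chrom, ds$snps$snp_id,
                         format_num(ds$snps$cm), format_num(ds$snps$bp),
                         minor_out, summ$major),
                   bim)
  write_text_lines(paste(ds$samples$family_id, ds$samples$individual_id,
                         ds$samples$paternal_id, ds$samples$maternal_id,
                         ds$samples$sex, ds$samples$phenotype),
                   fam)
  invisible(bed)
}

#' Read a PLINK binary BED/BIM/FAM fileset
#'
#' Only the SNP-major v1.00 variant (mode byte `0x01`) is supported;
#' individual-major files are rejected with a clear message.  Heterozygous
#' calls are reconstructed as "minor major" (BIM allele-1 then allele-2),
#' a fixed order that makes downstream text output byte-reproducible;
#' genotype semantics are unordered pairs throughout the package.
#'
#' @param bed,bim,fam Paths to the three files.
#' @return A [ped_dataset()].
#' @export
read_bed <- function(bed, bim, fam) {
  fam_fields <- ws_split(read_text_lines(fam))
  fam_fields <- fam_fields[lengths(fam_fields) > 0L]
  bad <- which(lengths(fam_fields) != 6L)
  if (length(bad)) {
    abort(sprintf("FAM row %d has %d fields; expected 6",
                  bad[[1L]], length(fam_fields[[bad[[1L]]]])),
          class = "pedkit_parse_error")
  }
  n <- length(fam_fields)
  smat <- if (n) matrix(unlist(fam_fields), ncol = 6L, byrow = TRUE) else
    matrix(character(), 0L, 6L)
  samples <- tibble(family_id = smat[, 1L], individual_id = smat[, 2L],
                    paternal_id = smat[, 3L], maternal_id = smat[, 4L],
                    sex = smat[, 5L], phenotype = smat[, 6L])

  bim_fields <- ws_split(read_text_lines(bim))
  bim_fields <- bim_fields[lengths(bim_fields) > 0L]
  bad <- which(lengths(bim_fields) != 6L)
  if (length(bad)) {
    abort(sprintf("BIM row %d has %d fields; expected 6",
                  bad[[1L]], length(bim_fields[[bad[[1L]]]])),
          class = "pedkit_parse_error")
  }
  m <- length(bim_fields)
  bmat <- if (m) matrix(unlist(bim_fields), ncol = 6L, byrow = TRUE) else
    matrix(character(), 0L, 6L)
  snps <- tibble(chrom = bmat[, 1L], snp_id = bmat[, 2L],
                 cm = as.numeric(bmat[, 3L]), bp = as.numeric(bmat[, 4L]))
  allele1 <- bmat[, 5L]  # minor
  allele2 <- bmat[, 6L]  # major

  sz <- file.info(bed)$size
  raw <- readBin(bed, "raw", n = sz)
  if (length(raw) < 3L || raw[[1L]] != as.raw(0x6C) || raw[[2L]] != as.raw(0x1B)) {
    abort(sprintf("not a BED file: %s (bad magic bytes)", bed),
          class = "pedkit_parse_error")
  }
  if (raw[[3L]] == as.raw(0x00)) {
    abort("individual-major BED files are not supported; re-export in SNP-major mode",
          class = "pedkit_parse_error")
  }
  if (raw[[3L]] != as.raw(0x01)) {
    abort("unrecognized BED mode byte", class = "pedkit_parse_error")
  }
  bpp <- ceiling(n / 4L)  # bytes per SNP block
  expected <- bpp * m
  payload <- raw[-(1:3)]
  if (length(payload) != expected) {
    abort(sprintf("BED payload is %d byte(s); expected ceil(%d/4) x %d = %d",
                  length(payload), n, m, expected),
          class = "pedkit_parse_error")
  }
  geno <- matrix("00", n, m)
  if (n && m) {
    ints <- as.integer(payload)
    quads <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                   (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
    dim(quads) <- c(4L * bpp, m)
    codes <- quads[seq_len(n), , drop = FALSE]
    for (j in seq_len(m)) {
      calls <- c(paste0(allele1[[j]], allele1[[j]]),       # 0: hom minor
                 "00",                                     # 1: missing
                 paste0(allele1[[j]], allele2[[j]]),       # 2: het
                 paste0(allele2[[j]], allele2[[j]]))       # 3: hom major
      geno[, j] <- calls[codes[, j] + 1L]
    }
  }
  ped_dataset(samples, snps, geno)
}
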