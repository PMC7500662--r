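#' Read a transposed PLINK TPED/TFAM fileset
#'
#' A TPED row holds the four marker columns followed by two allele tokens
#' per sample; the TFAM carries the six pedigree columns, one sample per
#' row.  SNP order follows TPED row order.  When a `.tsnp` sidecar is
#' supplied, the marker identifiers are replaced by the RS# column it
#' carries (one row per TPED row; the RS#-bearing column index is
#' configurable because the sidecar has no fixed published layout).
#'
#' @param tped,tfam Paths to the .tped and .tfam files.
#' @param tsnp Optional path to a whitespace-delimited .tsnp sidecar.
#' @param tsnp_col 1-based column of the .tsnp file holding the RS#
#'   identifiers (default 1).
#' @return A [ped_dataset()].
#' @export
read_tped <- function(tped, tfam, tsnp = NULL, tsnp_col = 1L) {
  tfam_fields <- ws_split(read_text_lines(tfam))
  tfam_fields <- tfam_fields[lengths(tfam_fields) > 0L]
  bad <- which(lengths(tfam_fields) != 6L)
  if (length(bad)) {
    abort(sprintf("TFAM row %d has %d fields; expected 6",
                  bad[[1L]], length(tfam_fields[[bad[[1L]]]])),
          class = "pedkit_parse_error")
  }
  n <- length(tfam_fields)
  smat <- if (n) matrix(unlist(tfam_fields), ncol = 6L, byrow = TRUE) else
    matrix(character(), 0L, 6L)
  samples <- tibble(family_id = smat[, 1L], individual_id = smat[, 2L],
                    paternal_id = smat[, 3L], maternal_id = smat[, 4L],
                    sex = smat[, 5L], phenotype = smat[, 6L])

  tped_fields <- ws_split(read_text_lines(tped))
  tped_fields <- tped_fields[lengths(tped_fields) > 0L]
  m <- length(tped_fields)
  expected <- 4L + 2L * n
  bad <- which(lengths(tped_fields) != expected)
  if (length(bad)) {
    abort(sprintf("TPED row %d has %d fields; expected %d (4 + 2 x %d samples)",
                  bad[[1L]], length(tped_fields[[bad[[1L]]]]), expected, n),
          class = "pedkit_parse_error")
  }
  tmat <- if (m) matrix(unlist(tped_fields), nrow = m, byrow = TRUE) else
    matrix(character(), 0L, expected)
  snps <- tibble(chrom = tmat[, 1L], snp_id = tmat[, 2L],
                 cm = as.numeric(tmat[, 3L]), bp = as.numeric(tmat[, 4L]))
  if (!is.null(tsnp)) {
    snps$snp_id <- read_tsnp_ids(tsnp, m, tsnp_col)
  }
  geno <- matrix("00", n, m)
  if (n && m) {
    allele_mat <- t(tmat[, -(1:4), drop = FALSE])  # 2n x m -> rows by sample
    a1 <- allele_mat[2L * seq_len(n) - 1L, , drop = FALSE]
    a2 <- allele_mat[2L * seq_len(n), , drop = FALSE]
    tokens <- cbind(a1, a2)
    if (any(nchar(tokens) != 1L)) {
      warn(sprintf("%d multi-character allele token(s) reduced to first character",
                   sum(nchar(tokens) != 1L)))
      a1[] <- reduce_allele(a1)
      a2[] <- reduce_allele(a2)
    }
    geno <- paste0(a1, a2)
    dim(geno) <- c(n, m)
  }
  ped_dataset(samples, snps, geno)
}

read_tsnp_ids <- function(tsnp, m, tsnp_col) {
  fields <- ws_split(read_text_lines(tsnp))
  fields <- fields[lengths(fields) > 0L]
  if (length(fields) != m) {
    abort(sprintf(".tsnp has %d row(s) but TPED has %d", length(fields), m),
          class = "pedkit_structure_error")
  }
  short <- which(lengths(fields) < tsnp_col)
  if (length(short)) {
    abort(sprintf(".tsnp row %d has no column %d", short[[1L]], tsnp_col),
          class = "pedkit_parse_error")
  }
  vapply(fields, `[[`, character(1), tsnp_col)
}

#' Write a transposed PLINK TPED/TFAM fileset
#'
#' One SNP per TPED row (chromosome, id, genetic distance, bp, then allele
#' pairs in sample order); the TFAM holds the six pedigree columns.
#'
#' @param ds A [ped_dataset()].
#' @param tped,tfam Output paths.
#' @return Invisibly, the .tped path.
#' @export
write_tped <- function(ds, tped, tfam) {
  n <- n_samples(ds); m <- n_snps(ds)
  left <- paste(ds$snps$chrom, ds$snps$snp_id,
                format_num(ds$snps$cm), format_num(ds$snps$bp))
  if (n && m) {
    allele_mat <- matrix("", m, 2L * n)
    tg <- t(ds$genotypes)  # m x n
    allele_mat[, 2L * seq_len(n) - 1L] <- substr(tg, 1L, 1L)
    allele_mat[, 2L * seq_len(n)] <- substr(tg, 2L, 2L)
    lines <- paste(left, paste_rows(allele_mat))
  } else {
    lines <- left
  }
  write_text_lines(lines, tped)
  write_text_lines(paste(ds$samples$family_id, ds$samples$individual_id,
                         ds$samples$paternal_id, ds$samples$maternal_id,
                         ds$samples$sex, ds$samples$phenotype),
                   tfam)
  invisible(tped)
}
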