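#' In-memory genotype dataset
#'
#' A `ped_dataset` is the hub of every conversion in pedkit: an ordered table
#' of samples (the six pedigree columns of a PED file), an ordered table of
#' markers, and a sample-by-marker grid of genotype calls.  Each call is a
#' two-character string holding the unordered allele pair (`"AC"`), with
#' `"00"` for a missing call.  Marker order is significant and preserved by
#' every operation unless documented otherwise.
#'
#' @param samples A data frame with character columns `family_id`,
#'   `individual_id`, `paternal_id`, `maternal_id`, `sex` (1 = male,
#'   2 = female, other = unknown) and `phenotype` (1 = control, 2 = case,
#'   quantitative, or 0/-9 = missing).
#' @param snps A data frame with columns `chrom`, `snp_id`, `cm` (genetic
#'   distance) and `bp` (physical position).  `snp_id` is the join key for
#'   splicing and alignment and must be unique.
#' @param genotypes A character matrix with one row per sample and one column
#'   per SNP; each cell is a two-character allele pair.  Half-missing calls
#'   (`"A0"`) are normalized to `"00"` with a warning.
#'
#' @return An object of class `ped_dataset`.
#' @examples
#' ds <- ped_dataset(
#'   samples = tibble::tibble(
#'     family_id = "F1", individual_id = "I1", paternal_id = "0",
#'     maternal_id = "0", sex = "1", phenotype = "2"),
#'   snps = tibble::tibble(chrom = "1", snp_id = "rs1", cm = 0, bp = 100),
#'   genotypes = matrix("AC", 1, 1))
#' glance(ds)
#' @export
ped_dataset <- function(samples, snps, genotypes) {
  sample_cols <- c("family_id", "individual_id", "paternal_id",
                   "maternal_id", "sex", "phenotype")
  snp_cols <- c("chrom", "snp_id", "cm", "bp")
  samples <- as_tibble(samples)
  snps <- as_tibble(snps)
  missing_s <- setdiff(sample_cols, names(samples))
  if (length(missing_s)) {
    abort(paste0("samples is missing column(s): ",
                 paste(missing_s, collapse = ", ")),
          class = "pedkit_structure_error")
  }
  missing_m <- setdiff(snp_cols, names(snps))
  if (length(missing_m)) {
    abort(paste0("snps is missing column(s): ",
                 paste(missing_m, collapse = ", ")),
          class = "pedkit_structure_error")
  }
  samples <- dplyr::mutate(samples[sample_cols],
                           dplyr::across(dplyr::everything(), as.character))
  snps <- dplyr::mutate(snps[snp_cols],
                        chrom = as.character(.data$chrom),
                        snp_id = as.character(.data$snp_id),
                        cm = as.numeric(.data$cm),
                        bp = as.numeric(.data$bp))
  if (anyDuplicated(snps$snp_id)) {
    dup <- unique(snps$snp_id[duplicated(snps$snp_id)])
    abort(paste0("duplicate snp_id(s): ", paste(head(dup, 5), collapse = ", ")),
          class = "pedkit_structure_error")
  }
  if (!is.matrix(genotypes) || !is.character(genotypes)) {
    genotypes <- matrix(as.character(genotypes),
                        nrow = nrow(samples), ncol = nrow(snps))
  }
  if (nrow(genotypes) != nrow(samples) || ncol(genotypes) != nrow(snps)) {
    abort(sprintf(
      "genotype grid is %d x %d but there are %d samples and %d SNPs",
      nrow(genotypes), ncol(genotypes), nrow(samples), nrow(snps)),
      class = "pedkit_structure_error")
  }
  genotypes <- fix_half_missing(genotypes)
  if (length(genotypes) && any(nchar(genotypes) != 2L)) {
    abort("genotype calls must be two-character allele pairs",
          class = "pedkit_structure_error")
  }
  dimnames(genotypes) <- NULL
  structure(list(samples = samples, snps = snps, genotypes = genotypes),
            class = "ped_dataset")
}

# half-missing calls ("A0", "0C", "AN", ...) become fully missing, with one
# warning per grid; PLINK applies the same convention on read
fix_half_missing <- function(geno) {
  if (!length(geno)) return(geno)
  a1 <- substr(geno, 1L, 1L)
  a2 <- substr(geno, 2L, 2L)
  m1 <- is_missing_char(a1)
  m2 <- is_missing_char(a2)
  half <- xor(m1, m2)
  if (any(half)) {
    warn(sprintf("%d half-missing call(s) normalized to fully missing",
                 sum(half)))
    geno[half] <- "00"
  }
  geno
}

# both '0' (pedigree convention) and 'N' (normalized alphabet) mean missing
is_missing_char <- function(ch) ch == "0" | ch == "N"

#' @export
print.ped_dataset <- function(x, ...) {
  cat(sprintf("<ped_dataset> %d sample(s) x %d SNP(s)\n",
              n_samples(x), n_snps(x)))
  if (n_samples(x) && n_snps(x)) {
    miss <- mean(is_missing_call(x$genotypes))
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  }
  invisible(x)
}

is_missing_call <- function(geno) {
  is_missing_char(substr(geno, 1L, 1L)) & is_missing_char(substr(geno, 2L, 2L))
}

#' Number of samples / SNPs in a dataset
#' @param ds A [ped_dataset()].
#' @return An integer count.
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' @rdname n_samples
#' @export
n_snps <- function(ds) nrow(ds$snps)

#' @export
glance.ped_dataset <- function(x, ...) {
  miss <- if (length(x$genotypes)) mean(is_missing_call(x$genotypes)) else 0
  tibble(
    n_samples = n_samples(x),
    n_snps = n_snps(x),
    n_cases = sum(x$samples$phenotype == "2"),
    n_controls = sum(x$samples$phenotype == "1"),
    missing_rate = miss
  )
}

#' @export
tidy.ped_dataset <- function(x, ...) {
  if (!n_samples(x) || !n_snps(x)) {
    return(tibble(individual_id = character(), snp_id = character(),
                  allele1 = character(), allele2 = character()))
  }
  tibble(
    individual_id = rep(x$samples$individual_id, times = n_snps(x)),
    snp_id = rep(x$snps$snp_id, each = n_samples(x)),
    allele1 = substr(as.vector(x$genotypes), 1L, 1L),
    allele2 = substr(as.vector(x$genotypes), 2L, 2L)
  )
}

# unordered-pair equality between two genotype grids of equal shape
same_genotypes <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!length(a)) return(TRUE)
  norm <- function(g) {
    x1 <- substr(g, 1L, 1L)
    x2 <- substr(g, 2L, 2L)
    x1[is_missing_char(x1)] <- "0"
    x2[is_missing_char(x2)] <- "0"
    ifelse(x1 <= x2, paste0(x1, x2), paste0(x2, x1))
  }
  all(norm(a) == norm(b))
}
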