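#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square test of observed genotype counts
#' against the counts expected under Hardy-Weinberg proportions at the
#' sample allele frequency.  With allele frequency `p` estimated from the
#' counts, expected counts are `n*p^2`, `2*n*p*q`, `n*q^2`.  A monomorphic
#' SNP (allele frequency 0 or 1) is reported as statistic 0, p-value 1 by
#' convention: with one allele there is no equilibrium to test.
#'
#' @param n_hom_major,n_het,n_hom_minor Non-negative integer vectors of
#'   genotype counts (recycled to a common length).
#' @return A tibble with columns `statistic` and `p.value`.
#' @examples
#' hwe_chi2(25, 50, 25)  # exactly at HWE: statistic 0
#' hwe_chi2(50, 0, 50)   # total heterozygote deficit: statistic 100
#' @export
hwe_chi2 <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- cbind(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("genotype counts must be finite and non-negative",
          class = "pedkit_config_error")
  }
  n <- rowSums(counts)
  if (any(n < 1)) {
    abort("at least one genotype observation is required",
          class = "pedkit_config_error")
  }
  p <- (2 * counts[, 1L] + counts[, 2L]) / (2 * n)
  q <- 1 - p
  exp_counts <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  stat <- numeric(length(n))
  poly <- p > 0 & p < 1
  if (any(poly)) {
    d <- (counts[poly, , drop = FALSE] - exp_counts[poly, , drop = FALSE])
    stat[poly] <- rowSums(d^2 / exp_counts[poly, , drop = FALSE])
  }
  pval <- ifelse(poly, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  tibble(statistic = unname(stat), p.value = unname(pval))
}

#' Missing-call rates per sample and per SNP
#'
#' @param ds A [ped_dataset()].
#' @return An object of class `missing_rates`: a list with tibbles
#'   `samples` (`individual_id`, `family_id`, `n_missing`, `rate` =
#'   missing calls / number of SNPs) and `snps` (`snp_id`, `n_missing`,
#'   `rate` = missing calls / number of samples).
#' @export
missing_rates <- function(ds) {
  miss <- is_missing_call(ds$genotypes)
  dim(miss) <- dim(ds$genotypes)
  per_sample <- if (n_snps(ds)) rowSums(miss) / n_snps(ds) else
    rep(0, n_samples(ds))
  per_snp <- if (n_samples(ds)) colSums(miss) / n_samples(ds) else
    rep(0, n_snps(ds))
  structure(list(
    samples = tibble(family_id = ds$samples$family_id,
                     individual_id = ds$samples$individual_id,
                     n_missing = if (n_snps(ds)) rowSums(miss) else
                       rep(0L, n_samples(ds)),
                     rate = per_sample),
    snps = tibble(snp_id = ds$snps$snp_id,
                  n_missing = if (n_samples(ds)) colSums(miss) else
                    rep(0L, n_snps(ds)),
                  rate = per_snp)
  ), class = "missing_rates")
}

#' @export
tidy.missing_rates <- function(x, ...) {
  bind_rows(
    tibble(dimension = "sample", id = x$samples$individual_id,
           rate = x$samples$rate),
    tibble(dimension = "snp", id = x$snps$snp_id, rate = x$snps$rate)
  )
}

#' @export
autoplot.missing_rates <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~dimension, scales = "free_y") +
    ggplot2::labs(x = "missing-call rate", y = "count",
                  title = "Missingness by sample and by SNP")
}

#' Quality-control thresholds
#'
#' All three filters default to disabled (`NULL`); a filter only runs when
#' its threshold is set.
#'
#' @param hwe_p_min Remove SNPs whose Hardy-Weinberg p-value is below this.
#' @param sample_missing_max Remove samples whose missing-call rate exceeds
#'   this fraction.
#' @param snp_missing_max Remove SNPs whose missing-call rate exceeds this
#'   fraction.
#' @return A `qc_thresholds` object.
#' @export
qc_thresholds <- function(hwe_p_min = NULL, sample_missing_max = NULL,
                          snp_missing_max = NULL) {
  for (v in list(hwe_p_min, sample_missing_max, snp_missing_max)) {
    if (!is.null(v) && !is_probability(v)) {
      abort("QC thresholds must be single values in [0, 1]",
            class = "pedkit_config_error")
    }
  }
  structure(list(hwe_p_min = hwe_p_min,
                 sample_missing_max = sample_missing_max,
                 snp_missing_max = snp_missing_max),
            class = "qc_thresholds")
}

#' Apply quality-control filters to a dataset
#'
#' Filters are applied in a fixed, documented order so results are
#' reproducible: (1) SNPs failing the per-SNP missing-rate threshold, then
#' (2) samples failing the per-sample missing-rate threshold, then (3) SNPs
#' failing the Hardy-Weinberg test — with rates and allele summaries
#' recomputed after each step, since removing samples changes per-SNP rates
#' and genotype counts.
#'
#' @param ds A [ped_dataset()].
#' @param thresholds A [qc_thresholds()] object.
#' @return A `qc_result`: list with `dataset` (the filtered
#'   [ped_dataset()]) and `report`, a tibble logging every removal with the
#'   step, the removed id, the measured value and the threshold it violated.
#' @export
apply_qc <- function(ds, thresholds = qc_thresholds()) {
  if (!inherits(thresholds, "qc_thresholds")) {
    thresholds <- do.call(qc_thresholds, as.list(thresholds))
  }
  report <- tibble(step = character(), type = character(), id = character(),
                   value = numeric(), threshold = numeric())

  if (!is.null(thresholds$snp_missing_max) && n_snps(ds) > 0L) {
    rates <- missing_rates(ds)$snps
    drop <- which(rates$rate > thresholds$snp_missing_max)
    if (length(drop)) {
      report <- bind_rows(report, tibble(
        step = "snp_missing", type = "snp", id = rates$snp_id[drop],
        value = rates$rate[drop], threshold = thresholds$snp_missing_max))
      ds <- drop_snps(ds, drop)
    }
  }
  if (!is.null(thresholds$sample_missing_max) && n_samples(ds) > 0L) {
    rates <- missing_rates(ds)$samples
    drop <- which(rates$rate > thresholds$sample_missing_max)
    if (length(drop)) {
      report <- bind_rows(report, tibble(
        step = "sample_missing", type = "sample",
        id = rates$individual_id[drop],
        value = rates$rate[drop], threshold = thresholds$sample_missing_max))
      ds <- drop_samples(ds, drop)
    }
  }
  if (!is.null(thresholds$hwe_p_min) && n_snps(ds) > 0L && n_samples(ds) > 0L) {
    counts <- genotype_counts(ds)
    keepable <- counts$n_hom_major + counts$n_het + counts$n_hom_minor > 0
    pvals <- rep(1, n_snps(ds))
    if (any(keepable)) {
      pvals[keepable] <- hwe_chi2(counts$n_hom_major[keepable],
                                  counts$n_het[keepable],
                                  counts$n_hom_minor[keepable])$p.value
    }
    drop <- which(pvals < thresholds$hwe_p_min)
    if (length(drop)) {
      report <- bind_rows(report, tibble(
        step = "hwe", type = "snp", id = ds$snps$snp_id[drop],
        value = pvals[drop], threshold = thresholds$hwe_p_min))
      ds <- drop_snps(ds, drop)
    }
  }
  structure(list(dataset = ds, report = report), class = "qc_result")
}

#' Genotype-class counts per SNP
#'
#' @param ds A [ped_dataset()].
#' @return A tibble with `snp_id`, `n_hom_major`, `n_het`, `n_hom_minor`,
#'   `n_missing` per SNP.
#' @export
genotype_counts <- function(ds) {
  summ <- allele_summary(ds)
  geno <- ds$genotypes
  out <- tibble(snp_id = ds$snps$snp_id,
                n_hom_major = integer(n_snps(ds)),
                n_het = integer(n_snps(ds)),
                n_hom_minor = integer(n_snps(ds)),
                n_missing = integer(n_snps(ds)))
  for (j in seq_len(n_snps(ds))) {
    a1 <- substr(geno[, j], 1L, 1L)
    a2 <- substr(geno[, j], 2L, 2L)
    miss <- is_missing_char(a1) | is_missing_char(a2)
    maj <- summ$major[[j]]
    out$n_missing[[j]] <- sum(miss)
    out$n_hom_major[[j]] <- sum(!miss & a1 == maj & a2 == maj)
    out$n_het[[j]] <- sum(!miss & a1 != a2)
    out$n_hom_minor[[j]] <- sum(!miss & a1 == a2 & a1 != maj)
  }
  out
}

drop_snps <- function(ds, idx) {
  if (!length(idx)) return(ds)
  keep <- setdiff(seq_len(n_snps(ds)), idx)
  ped_dataset(ds$samples, ds$snps[keep, , drop = FALSE],
              ds$genotypes[, keep, drop = FALSE])
}

drop_samples <- function(ds, idx) {
  if (!length(idx)) return(ds)
  keep <- setdiff(seq_len(n_samples(ds)), idx)
  ped_dataset(ds$samples[keep, , drop = FALSE], ds$snps,
              ds$genotypes[keep, , drop = FALSE])
}

#' @export
tidy.qc_result <- function(x, ...) x$report

#' @export
glance.qc_result <- function(x, ...) {
  tibble(n_samples_kept = n_samples(x$dataset),
         n_snps_kept = n_snps(x$dataset),
         n_samples_removed = sum(x$report$type == "sample"),
         n_snps_removed = sum(x$report$type == "snp"))
}

#' @export
print.qc_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<qc_result> kept %d sample(s), %d SNP(s); removed %d sample(s), %d SNP(s)\n",
              g$n_samples_kept, g$n_snps_kept,
              g$n_samples_removed, g$n_snps_removed))
  invisible(x)
}
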