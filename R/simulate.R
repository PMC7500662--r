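#' Simulate a genotype dataset under Hardy-Weinberg proportions
#'
#' Generates a case/control PED-style dataset for testing conversions
#' without any external download.  Per SNP, a minor-allele frequency is
#' drawn uniformly from `maf_range`, two distinct allele letters are drawn
#' from `alleles`, genotypes are drawn from the Hardy-Weinberg class
#' probabilities (p², 2pq, q²) — not as independent allele draws — so that
#' the chi-square QC test is calibrated against the generator, and calls
#' are then masked to missing at `missing_rate`.  Phenotypes are `2` (case)
#' for the first `ceiling(case_fraction * n)` samples and `1` (control)
#' otherwise.  The same seed always yields the identical dataset.
#'
#' @param n_samples,n_snps Non-negative dimensions (0 gives a degenerate
#'   but valid dataset).
#' @param maf_range Length-2 interval in (0, 0.5] from which each SNP's
#'   minor-allele frequency is drawn (a single value fixes the MAF).
#' @param missing_rate Fraction of calls masked to missing.
#' @param case_fraction Fraction of samples labelled as cases.
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @param alleles Character set the two allele letters are drawn from.
#' @return A [ped_dataset()].
#' @examples
#' sim_ped_dataset(6, 3, seed = 42)
#' @export
sim_ped_dataset <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                            missing_rate = 0, case_fraction = 0.5,
                            seed = NULL, alleles = c("A", "C", "G", "T")) {
  if (n_samples < 0 || n_snps < 0) {
    abort("n_samples and n_snps must be non-negative",
          class = "pedkit_config_error")
  }
  if (length(maf_range) == 1L) maf_range <- rep(maf_range, 2L)
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[[1L]] > maf_range[[2L]]) {
    abort("maf_range must be an interval within (0, 0.5]",
          class = "pedkit_config_error")
  }
  if (!is_probability(missing_rate) || !is_probability(case_fraction)) {
    abort("missing_rate and case_fraction must be in [0, 1]",
          class = "pedkit_config_error")
  }
  if (length(alleles) < 2L) {
    abort("need at least two allele letters", class = "pedkit_config_error")
  }
  build <- function() {
    geno <- matrix("00", n_samples, n_snps)
    for (j in seq_len(n_snps)) {
      letters2 <- sample(alleles, 2L)
      maj <- letters2[[1L]]; mnr <- letters2[[2L]]
      q <- runif(1, maf_range[[1L]], maf_range[[2L]])
      p <- 1 - q
      g <- sample.int(3L, n_samples, replace = TRUE,
                      prob = c(p^2, 2 * p * q, q^2))
      calls <- c(paste0(maj, maj), paste0(maj, mnr), paste0(mnr, mnr))[g]
      if (missing_rate > 0 && n_samples > 0L) {
        calls[runif(n_samples) < missing_rate] <- "00"
      }
      geno[, j] <- calls
    }
    n_cases <- ceiling(case_fraction * n_samples)
    samples <- tibble(
      family_id = paste0("F", seq_len(n_samples)),
      individual_id = paste0("I", seq_len(n_samples)),
      paternal_id = rep("0", n_samples),
      maternal_id = rep("0", n_samples),
      sex = if (n_samples) as.character(sample(1:2, n_samples, TRUE)) else
        character(),
      phenotype = c(rep("2", n_cases), rep("1", n_samples - n_cases))
    )
    snps <- tibble(
      chrom = rep("1", n_snps),
      snp_id = paste0("rs", seq_len(n_snps)),
      cm = rep(0, n_snps),
      bp = if (n_snps) seq_len(n_snps) * 1000 else numeric()
    )
    ped_dataset(samples, snps, geno)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate a pair of PED filesets for splicing tests
#'
#' Writes two PED/MAP filesets sharing a controlled number of samples
#' (identical six-column pedigree prefixes *and* genotypes for the shared
#' samples) over a common SNP panel, so the spliced sample count is known
#' in advance: `n_a + n_b - n_shared`.
#'
#' @param dir Output directory.
#' @param n_a,n_b Sample counts of the two filesets.
#' @param n_shared Number of samples of A duplicated into B.
#' @param n_snps Number of SNPs on the common panel.
#' @param seed Integer seed.
#' @return A list with the two filesets' paths and
#'   `expected_spliced_samples`.
#' @export
sim_splice_pair <- function(dir, n_a = 4, n_b = 6, n_shared = 0,
                            n_snps = 5, seed = 1) {
  stopifnot(n_shared <= min(n_a, n_b))
  ds <- sim_ped_dataset(n_a + n_b - n_shared, n_snps, seed = seed)
  idx_a <- seq_len(n_a)
  idx_b <- c(seq_len(n_shared), n_a + seq_len(n_b - n_shared))
  ds_a <- ped_dataset(ds$samples[idx_a, ], ds$snps,
                      ds$genotypes[idx_a, , drop = FALSE])
  ds_b <- ped_dataset(ds$samples[idx_b, ], ds$snps,
                      ds$genotypes[idx_b, , drop = FALSE])
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- list(ped = file.path(dir, "a.ped"), map = file.path(dir, "a.map"))
  b <- list(ped = file.path(dir, "b.ped"), map = file.path(dir, "b.map"))
  write_ped(ds_a, a$ped, a$map)
  write_ped(ds_b, b$ped, b$map)
  list(a = a, b = b,
       expected_spliced_samples = n_a + n_b - n_shared)
}

#' Export one simulated dataset to a suite of formats
#'
#' Builds one directory per requested format containing the exported files
#' plus a `manifest.tsv` recording the expected dimensions — a
#' self-describing fixture tree for downstream tests.
#'
#' @param dir Root output directory.
#' @param formats Character vector of format ids: `"ped"`, `"bed"`,
#'   `"tped"` or any id in [format_registry()].
#' @param n_samples,n_snps,seed,... Passed to [sim_ped_dataset()].
#' @return Invisibly, the manifest tibble.
#' @export
sim_fixture_suite <- function(dir, formats = c("ped", "bed", "tped"),
                              n_samples = 8, n_snps = 5, seed = 1, ...) {
  ds <- sim_ped_dataset(n_samples, n_snps, seed = seed, ...)
  known <- c("ped", "bed", "tped", format_registry()$format)
  bad <- setdiff(formats, known)
  if (length(bad)) {
    abort(paste0("unknown format(s): ", paste(bad, collapse = ", ")),
          class = "pedkit_config_error")
  }
  rows <- lapply(formats, function(f) {
    sub <- file.path(dir, f)
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    files <- switch(f,
      ped = {
        write_ped(ds, file.path(sub, "data.ped"), file.path(sub, "data.map"))
        c("data.ped", "data.map")
      },
      bed = {
        write_bed(ds, file.path(sub, "data.bed"), file.path(sub, "data.bim"),
                  file.path(sub, "data.fam"))
        c("data.bed", "data.bim", "data.fam")
      },
      tped = {
        write_tped(ds, file.path(sub, "data.tped"), file.path(sub, "data.tfam"))
        c("data.tped", "data.tfam")
      },
      {
        out <- export_dataset(ds, f, file.path(sub, paste0("data.", f)))
        basename(out)
      })
    tibble(format = f, n_samples = n_samples(ds), n_snps = n_snps(ds),
           files = paste(files, collapse = ";"))
  })
  manifest <- bind_rows(rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
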