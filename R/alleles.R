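#' Reduce a raw allele token to its allele character
#'
#' Multi-character allele tokens (for example indel codes such as `"ACG"`)
#' are represented by their first character throughout the package; `"0"`
#' stays the missing code.
#'
#' @param raw Character vector of non-empty allele tokens.
#' @return Character vector of single characters.
#' @examples
#' reduce_allele(c("ACG", "T", "0"))
#' @export
reduce_allele <- function(raw) {
  if (any(!nzchar(raw))) {
    abort("empty allele token", class = "pedkit_parse_error")
  }
  substr(raw, 1L, 1L)
}

# per-column allele summary from the two allele-character vectors.
# Returns a one-row data.frame; `label` names the SNP in error messages.
summarize_column <- function(a1, a2, label = "?") {
  miss1 <- is_missing_char(a1)
  miss2 <- is_missing_char(a2)
  chars <- c(a1[!miss1], a2[!miss2])
  missing_calls <- sum(miss1 & miss2)
  # ASCII (code-point) order, independent of the session locale
  lv <- unique(chars)
  lv <- lv[order(vapply(lv, utf8ToInt, integer(1)))]
  if (length(lv) > 2L) {
    abort(sprintf("SNP %s is multi-allelic: alleles %s", label,
                  paste(lv, collapse = ", ")),
          class = "pedkit_multiallelic_error")
  }
  if (length(lv) == 0L) {
    return(data.frame(major = "0", minor = "0", major_count = 0L,
                      minor_count = 0L, missing_calls = missing_calls,
                      is_tied = FALSE, is_monomorphic = TRUE,
                      stringsAsFactors = FALSE))
  }
  counts <- vapply(lv, function(ch) sum(chars == ch), integer(1))
  if (length(lv) == 1L) {
    return(data.frame(major = lv, minor = "0", major_count = counts[[1L]],
                      minor_count = 0L, missing_calls = missing_calls,
                      is_tied = FALSE, is_monomorphic = TRUE,
                      stringsAsFactors = FALSE))
  }
  # tie broken by ASCII order: the lower code becomes the major allele
  if (counts[[1L]] >= counts[[2L]]) {
    maj <- 1L; mnr <- 2L
  } else {
    maj <- 2L; mnr <- 1L
  }
  data.frame(major = lv[[maj]], minor = lv[[mnr]],
             major_count = unname(counts[[maj]]),
             minor_count = unname(counts[[mnr]]),
             missing_calls = missing_calls,
             is_tied = unname(counts[[1L]] == counts[[2L]] && counts[[1L]] > 0L),
             is_monomorphic = FALSE, stringsAsFactors = FALSE)
}

#' Summarize major/minor alleles per SNP
#'
#' Tallies every non-missing allele occurrence in each SNP column and
#' determines the major (more frequent) and minor allele.  Ties are broken
#' by ASCII order (the lower character code becomes the major allele) so
#' results are deterministic; monomorphic columns report `"0"` as the minor
#' allele.  A column with more than two distinct allele characters is an
#' error naming the SNP.
#'
#' @param x A [ped_dataset()], or a character vector of two-character calls
#'   for a single SNP column.
#' @param ... Unused.
#' @return A tibble with one row per SNP: `snp_id`, `major`, `minor`,
#'   `major_count`, `minor_count`, `missing_calls`, `is_tied`,
#'   `is_monomorphic`, `maf`.  For every column,
#'   `major_count + minor_count + 2 * missing_calls == 2 * n_samples`.
#' @examples
#' allele_summary(c("AA", "AC", "CC"))
#' @export
allele_summary <- function(x, ...) UseMethod("allele_summary")

#' @export
allele_summary.character <- function(x, ...) {
  res <- summarize_column(substr(x, 1L, 1L), substr(x, 2L, 2L))
  res <- cbind(data.frame(snp_id = NA_character_, stringsAsFactors = FALSE), res)
  finish_summary(res)
}

#' @export
allele_summary.ped_dataset <- function(x, ...) {
  m <- n_snps(x)
  if (m == 0L) {
    return(finish_summary(data.frame(
      snp_id = character(), major = character(), minor = character(),
      major_count = integer(), minor_count = integer(),
      missing_calls = integer(), is_tied = logical(),
      is_monomorphic = logical(), stringsAsFactors = FALSE)))
  }
  a1 <- substr(x$genotypes, 1L, 1L)
  a2 <- substr(x$genotypes, 2L, 2L)
  dim(a1) <- dim(x$genotypes)
  dim(a2) <- dim(x$genotypes)
  rows <- lapply(seq_len(m), function(j) {
    summarize_column(a1[, j], a2[, j],
                     label = sprintf("%s (column %d)", x$snps$snp_id[[j]], j))
  })
  res <- cbind(data.frame(snp_id = x$snps$snp_id, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  finish_summary(res)
}

finish_summary <- function(res) {
  res <- as_tibble(res)
  tot <- res$major_count + res$minor_count
  res$maf <- ifelse(tot > 0, res$minor_count / tot, NA_real_)
  class(res) <- c("allele_summary", class(res))
  res
}

#' @export
autoplot.allele_summary <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$maf), ],
                  ggplot2::aes(x = .data$maf)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "minor allele frequency", y = "SNPs",
                  title = "Minor allele frequency spectrum")
}

#' Normalize genotypes to the D/d/N alphabet
#'
#' Rewrites every SNP column so the major allele is `"D"`, the minor allele
#' `"d"` and a missing allele `"N"`.  Normalization makes the major/minor
#' composition of each column visible at a glance when checking a file by
#' hand, and is idempotent: normalizing a normalized dataset changes
#' nothing ('D' sorts before 'd' in ASCII, so the tie-break keeps 'D'
#' major).
#'
#' @param ds A [ped_dataset()].
#' @return A [ped_dataset()] with the recoded grid.
#' @examples
#' ds <- sim_ped_dataset(4, 2, seed = 1)
#' normalize_genotypes(ds)$genotypes
#' @export
normalize_genotypes <- function(ds) {
  summ <- allele_summary(ds)
  geno <- ds$genotypes
  if (length(geno)) {
    a1 <- substr(geno, 1L, 1L); dim(a1) <- dim(geno)
    a2 <- substr(geno, 2L, 2L); dim(a2) <- dim(geno)
    for (j in seq_len(ncol(geno))) {
      map <- c(setNames("D", summ$major[[j]]), setNames("d", summ$minor[[j]]))
      p1 <- remap_allele(a1[, j], map)
      p2 <- remap_allele(a2[, j], map)
      # canonical heterozygote order: major allele first
      geno[, j] <- ifelse(p1 == "d" & p2 == "D", "Dd", paste0(p1, p2))
    }
  }
  ped_dataset(ds$samples, ds$snps, geno)
}

remap_allele <- function(ch, map) {
  out <- unname(map[ch])
  out[is_missing_char(ch)] <- "N"
  out[is.na(out)] <- "N"
  out
}

#' Swap allele characters of tied SNPs
#'
#' For every SNP whose major and minor alleles occur equally often, the two
#' allele characters are exchanged in that column (`"AA AC CC"` becomes
#' `"CC CA AA"`).  The SNP's information content is unchanged; the swap
#' only relabels which of the two equally frequent alleles is written
#' first, which is useful when comparing files.  Applying the operation
#' twice restores the original dataset; SNPs without a tie are untouched.
#'
#' @param ds A [ped_dataset()].
#' @return A [ped_dataset()] with tied columns swapped.
#' @export
swap_tied_alleles <- function(ds) {
  summ <- allele_summary(ds)
  geno <- ds$genotypes
  for (j in which(summ$is_tied)) {
    a1 <- substr(geno[, j], 1L, 1L)
    a2 <- substr(geno[, j], 2L, 2L)
    map <- c(setNames(summ$minor[[j]], summ$major[[j]]),
             setNames(summ$major[[j]], summ$minor[[j]]))
    swap1 <- unname(map[a1]); swap1[is.na(swap1)] <- a1[is.na(swap1)]
    swap2 <- unname(map[a2]); swap2[is.na(swap2)] <- a2[is.na(swap2)]
    geno[, j] <- paste0(swap1, swap2)
  }
  ped_dataset(ds$samples, ds$snps, geno)
}
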