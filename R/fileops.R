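#' Compare two files sequentially or by a reference column
#'
#' Text files are compared field-wise after whitespace normalization (runs
#' of spaces/tabs collapse to one and leading/trailing whitespace is
#' stripped), so formatting-only differences never count.  In
#' `"sequential"` mode rows are paired by position, empty rows included: a
#' row paired with an unequal row — or with a surplus/empty row — counts
#' as one differing row, with every affected 1-based column index
#' recorded.  In `"reference"` mode rows are paired by the value in
#' `ref_col` regardless of order; keys present in only one file are
#' reported separately (`rows_only_in_a`/`b`) and are not counted as
#' differing rows.  Files containing NUL bytes are compared bytewise in
#' sequential mode.
#'
#' @param a,b Paths of the two files.
#' @param mode `"sequential"` or `"reference"`.
#' @param ref_col 1-based reference column; required in reference mode.
#' @return A `file_comparison` object; its `differing_rows` tibble has one
#'   row per difference with a locator (`row` number, or `key` value in
#'   reference mode) and the list of differing column indices.  An empty
#'   report means the files are equivalent under whitespace normalization.
#' @export
compare_files <- function(a, b, mode = c("sequential", "reference"),
                          ref_col = NULL) {
  mode <- match.arg(mode)
  if (mode == "reference" && is.null(ref_col)) {
    abort("reference mode requires ref_col", class = "pedkit_config_error")
  }
  if (looks_binary(a) || looks_binary(b)) {
    if (mode == "reference") {
      abort("reference mode is only defined for text files",
            class = "pedkit_config_error")
    }
    return(compare_binary(a, b))
  }
  fa <- ws_split(read_text_lines(a))
  fb <- ws_split(read_text_lines(b))
  if (mode == "sequential") compare_sequential(fa, fb) else
    compare_reference(fa, fb, ref_col)
}

compare_binary <- function(a, b) {
  ra <- readBin(a, "raw", n = file.info(a)$size)
  rb <- readBin(b, "raw", n = file.info(b)$size)
  len <- min(length(ra), length(rb))
  diffs <- which(ra[seq_len(len)] != rb[seq_len(len)])
  if (length(ra) != length(rb)) {
    diffs <- c(diffs, seq(len + 1L, max(length(ra), length(rb))))
  }
  structure(list(
    mode = "binary", ref_col = NULL,
    differing_rows = tibble(row = diffs, columns = rep(list(1L),
                                                       length(diffs))),
    rows_only_in_a = character(), rows_only_in_b = character(),
    n_rows_a = length(ra), n_rows_b = length(rb)),
    class = "file_comparison")
}

compare_sequential <- function(fa, fb) {
  n <- max(length(fa), length(fb))
  rows <- integer(0)
  cols <- list()
  for (i in seq_len(n)) {
    ra <- if (i <= length(fa)) fa[[i]] else NULL
    rb <- if (i <= length(fb)) fb[[i]] else NULL
    d <- diff_columns(ra, rb)
    if (length(d)) {
      rows <- c(rows, i)
      cols[[length(cols) + 1L]] <- d
    }
  }
  structure(list(mode = "sequential", ref_col = NULL,
                 differing_rows = tibble(row = rows, columns = cols),
                 rows_only_in_a = character(), rows_only_in_b = character(),
                 n_rows_a = length(fa), n_rows_b = length(fb)),
            class = "file_comparison")
}

# differing 1-based field indices between two rows; a surplus or empty
# counterpart flags every field of the longer row (minimum 1)
diff_columns <- function(ra, rb) {
  la <- length(ra %||% character(0))
  lb <- length(rb %||% character(0))
  if (la == 0L && lb == 0L) return(integer(0))
  if (la == 0L || lb == 0L) return(seq_len(max(la, lb)))
  len <- min(la, lb)
  d <- which(ra[seq_len(len)] != rb[seq_len(len)])
  if (la != lb) d <- c(d, seq(len + 1L, max(la, lb)))
  d
}

compare_reference <- function(fa, fb, ref_col) {
  fa <- fa[lengths(fa) > 0L]
  fb <- fb[lengths(fb) > 0L]
  key_of <- function(fields, which_file) {
    short <- which(lengths(fields) < ref_col)
    if (length(short)) {
      abort(sprintf("file %s row %d has no column %d", which_file,
                    short[[1L]], ref_col),
            class = "pedkit_parse_error")
    }
    keys <- vapply(fields, `[[`, character(1), ref_col)
    dup <- unique(keys[duplicated(keys)])
    if (length(dup)) {
      abort(sprintf("duplicate reference key(s) in file %s: %s", which_file,
                    paste(head(dup, 5), collapse = ", ")),
            class = "pedkit_comparison_error")
    }
    keys
  }
  ka <- key_of(fa, "A")
  kb <- key_of(fb, "B")
  shared <- intersect(ka, kb)
  keys <- character(0)
  cols <- list()
  for (k in shared) {
    d <- diff_columns(fa[[match(k, ka)]], fb[[match(k, kb)]])
    if (length(d)) {
      keys <- c(keys, k)
      cols[[length(cols) + 1L]] <- d
    }
  }
  structure(list(mode = "reference", ref_col = ref_col,
                 differing_rows = tibble(key = keys, columns = cols),
                 rows_only_in_a = setdiff(ka, kb),
                 rows_only_in_b = setdiff(kb, ka),
                 n_rows_a = length(fa), n_rows_b = length(fb)),
            class = "file_comparison")
}

#' @export
print.file_comparison <- function(x, ...) {
  cat(sprintf("<file_comparison> mode=%s%s\n", x$mode,
              if (!is.null(x$ref_col)) sprintf(" (reference column %d)",
                                               x$ref_col) else ""))
  cat(sprintf("  differing rows: %d\n", nrow(x$differing_rows)))
  if (x$mode == "reference") {
    cat(sprintf("  keys only in A: %d; only in B: %d\n",
                length(x$rows_only_in_a), length(x$rows_only_in_b)))
  }
  invisible(x)
}

#' @export
tidy.file_comparison <- function(x, ...) {
  dr <- x$differing_rows
  if (!nrow(dr)) {
    return(tibble(locator = character(), column = integer()))
  }
  loc <- as.character(dr[[1L]])
  tibble(locator = rep(loc, lengths(dr$columns)),
         column = unlist(dr$columns))
}

#' @export
glance.file_comparison <- function(x, ...) {
  tibble(mode = x$mode, n_differing_rows = nrow(x$differing_rows),
         n_only_in_a = length(x$rows_only_in_a),
         n_only_in_b = length(x$rows_only_in_b),
         identical = nrow(x$differing_rows) == 0L &&
           length(x$rows_only_in_a) == 0L && length(x$rows_only_in_b) == 0L)
}

#' Write a comparison report to a file
#'
#' Emits the human-readable report alongside a machine-readable TSV
#' (`<path>.tsv`) with one row per differing row/column pair.
#'
#' @param x A `file_comparison`.
#' @param path Output path for the text report.
#' @return Invisibly, `path`.
#' @export
write_comparison_report <- function(x, path) {
  g <- glance(x)
  lines <- c(sprintf("mode: %s", x$mode),
             if (!is.null(x$ref_col)) sprintf("reference column: %d", x$ref_col),
             sprintf("differing rows: %d", g$n_differing_rows))
  dr <- x$differing_rows
  for (i in seq_len(nrow(dr))) {
    lines <- c(lines, sprintf("  %s %s: column(s) %s",
                              if (x$mode == "reference") "key" else "row",
                              as.character(dr[[1L]][[i]]),
                              paste(dr$columns[[i]], collapse = ", ")))
  }
  if (length(x$rows_only_in_a)) {
    lines <- c(lines, paste("keys only in A:",
                            paste(x$rows_only_in_a, collapse = ", ")))
  }
  if (length(x$rows_only_in_b)) {
    lines <- c(lines, paste("keys only in B:",
                            paste(x$rows_only_in_b, collapse = ", ")))
  }
  write_text_lines(lines, path)
  td <- tidy(x)
  utils::write.table(td, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# transpose
# ---------------------------------------------------------------------------

#' Transpose a delimited text file
#'
#' Writes cell (i, j) of the input at (j, i) of the output with a
#' single-space delimiter.  Two operating modes produce byte-identical
#' output: `"speed"` materializes the whole grid in memory;
#' `"memory"` makes multiple passes over the input, transposing a block of
#' columns per pass and never holding the full grid.  `"auto"` picks the
#' memory-first mode when the estimated in-memory requirement (grid bytes
#' times a safety factor of 1.2) exceeds `mem_limit`.
#'
#' @param path_in,path_out Input and output paths.
#' @param mode `"auto"`, `"speed"` or `"memory"`.
#' @param mem_limit Memory budget in bytes used by `"auto"` (default 1 GiB,
#'   configurable via `options(pedkit.mem_limit = )`).
#' @param block_cols Columns transposed per pass in memory-first mode.
#' @return Invisibly, `path_out`.
#' @export
transpose_file <- function(path_in, path_out,
                           mode = c("auto", "speed", "memory"),
                           mem_limit = getOption("pedkit.mem_limit", 2^30),
                           block_cols = 512L) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    est <- file.info(path_in)$size * 2 * 1.2
    mode <- if (est > mem_limit) "memory" else "speed"
    inform(sprintf("transpose: auto mode selected %s-first (estimated %.0f bytes)",
                   mode, est))
  }
  if (mode == "speed") {
    fields <- ws_split(read_text_lines(path_in))
    fields <- fields[lengths(fields) > 0L]
    assert_rectangular(fields, "transpose input")
    if (!length(fields)) {
      write_text_lines(character(0), path_out)
      return(invisible(path_out))
    }
    mat <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
    write_text_lines(paste_rows(t(mat)), path_out)
  } else {
    transpose_memory_first(path_in, path_out, block_cols)
  }
  invisible(path_out)
}

# multi-pass block transpose: pass p extracts columns in [lo, hi] from every
# row and appends them as output rows; working set is one column block
transpose_memory_first <- function(path_in, path_out, block_cols) {
  # first pass: establish the column count and check rectangularity
  ncols <- NULL
  con <- file(path_in, open = "r")
  row_i <- 0L
  repeat {
    lines <- readLines(con, n = 2048L, warn = FALSE)
    if (!length(lines)) break
    for (ln in lines) {
      f <- ws_split(ln)[[1L]]
      if (!length(f)) next
      row_i <- row_i + 1L
      if (is.null(ncols)) {
        ncols <- length(f)
      } else if (length(f) != ncols) {
        close(con)
        abort(sprintf("transpose input is ragged: row %d has %d fields, row 1 has %d",
                      row_i, length(f), ncols),
              class = "pedkit_parse_error")
      }
    }
  }
  close(con)
  out <- file(path_out, open = "wb")
  on.exit(close(out))
  if (is.null(ncols)) return(invisible(path_out))
  for (lo in seq(1L, ncols, by = block_cols)) {
    hi <- min(lo + block_cols - 1L, ncols)
    block <- vector("list", row_i)
    con <- file(path_in, open = "r")
    i <- 0L
    repeat {
      lines <- readLines(con, n = 2048L, warn = FALSE)
      if (!length(lines)) break
      for (ln in lines) {
        f <- ws_split(ln)[[1L]]
        if (!length(f)) next
        i <- i + 1L
        block[[i]] <- f[lo:hi]
      }
    }
    close(con)
    bm <- matrix(unlist(block), ncol = hi - lo + 1L, byrow = TRUE)
    writeLines(paste_rows(t(bm)), out, sep = "\n")
  }
  invisible(path_out)
}

# ---------------------------------------------------------------------------
# insert / delete
# ---------------------------------------------------------------------------

#' Insert rows or columns into a delimited text file
#'
#' Any number of insertions is applied in declared order, each against the
#' file as already modified by the previous ones.  Content patterns use
#' the wildcard language of [expand_wildcard()]; a serial wildcard expands
#' along the inserted row/column, a literal pattern is recycled.  All
#' positions are validated against the current dimensions before anything
#' is written.
#'
#' @param path_in,path_out Input and output paths.
#' @param spec A data frame (or list of lists) with elements `axis`
#'   (`"row"`/`"col"`), `position` (1-based, up to dimension + 1) and
#'   `pattern`.
#' @return Invisibly, `path_out`.
#' @export
insert_rows_cols <- function(path_in, path_out, spec) {
  spec <- as_edit_spec(spec)
  fields <- ws_split(read_text_lines(path_in))
  fields <- fields[lengths(fields) > 0L]
  assert_rectangular(fields, "insert input")
  mat <- if (length(fields)) {
    matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  } else {
    matrix(character(), 0L, 0L)
  }
  for (i in seq_len(nrow(spec))) {
    axis <- spec$axis[[i]]
    pos <- spec$position[[i]]
    limit <- if (axis == "row") nrow(mat) + 1L else ncol(mat) + 1L
    if (pos < 1L || pos > limit) {
      abort(sprintf("insert position %d out of range (1..%d)", pos, limit),
            class = "pedkit_config_error")
    }
    span <- if (axis == "row") ncol(mat) else nrow(mat)
    vals <- expand_wildcard(spec$pattern[[i]], max(span, 1L))
    if (length(vals) == 1L) vals <- rep(vals, max(span, 1L))
    if (axis == "row") {
      mat <- rbind(mat[seq_len(pos - 1L), , drop = FALSE],
                   vals,
                   mat[seq_len(nrow(mat)) >= pos, , drop = FALSE])
    } else {
      mat <- cbind(mat[, seq_len(pos - 1L), drop = FALSE],
                   vals,
                   mat[, seq_len(ncol(mat)) >= pos, drop = FALSE])
    }
    dimnames(mat) <- NULL
  }
  write_text_lines(paste_rows(mat), path_out)
  invisible(path_out)
}

as_edit_spec <- function(spec) {
  if (is.data.frame(spec)) return(spec)
  bind_rows(lapply(spec, function(s) {
    tibble(axis = s$axis %||% s[[1L]], position = as.integer(s$position %||% s[[2L]]),
           pattern = as.character(s$pattern %||% s[[3L]]))
  }))
}

#' Delete rows and/or columns from a delimited text file
#'
#' All listed rows and columns are removed in one pass; the order of the
#' survivors is preserved.
#'
#' @param path_in,path_out Input and output paths.
#' @param rows,cols Integer sets of 1-based indices to remove.
#' @return Invisibly, `path_out`.
#' @export
delete_rows_cols <- function(path_in, path_out, rows = integer(0),
                             cols = integer(0)) {
  fields <- ws_split(read_text_lines(path_in))
  fields <- fields[lengths(fields) > 0L]
  assert_rectangular(fields, "delete input")
  mat <- if (length(fields)) {
    matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  } else {
    matrix(character(), 0L, 0L)
  }
  bad_r <- setdiff(rows, seq_len(nrow(mat)))
  bad_c <- setdiff(cols, seq_len(ncol(mat)))
  if (length(bad_r) || length(bad_c)) {
    abort(sprintf("out-of-range index(es): %s",
                  paste(c(bad_r, bad_c), collapse = ", ")),
          class = "pedkit_config_error")
  }
  mat <- mat[setdiff(seq_len(nrow(mat)), rows),
             setdiff(seq_len(ncol(mat)), cols), drop = FALSE]
  write_text_lines(paste_rows(mat), path_out)
  invisible(path_out)
}

# ---------------------------------------------------------------------------
# splicing
# ---------------------------------------------------------------------------

#' Splice the samples of two PED filesets
#'
#' Sample-wise merging: the output holds every sample of file A followed
#' by the samples of file B, aligned on A's SNP order (B-only SNPs are
#' appended after A's, in B's order).  A genotype absent from one file at
#' a SNP present in the other is set missing.  Samples whose six pedigree
#' columns match a sample of A are dropped from B — the first file's copy
#' wins.  Exactly two inputs are spliced per call; call repeatedly for
#' more files.
#'
#' @param ped_a,map_a,ped_b,map_b Input PED/MAP paths (maps optional).
#' @param ped_out,map_out Output paths.
#' @return Invisibly, the spliced [ped_dataset()].
#' @export
splice_ped <- function(ped_a, ped_b, ped_out, map_a = NULL, map_b = NULL,
                       map_out = NULL) {
  a <- read_ped(ped_a, map_a)
  b <- read_ped(ped_b, map_b)
  out <- splice_datasets(a, b)
  write_ped(out, ped_out, map_out)
  invisible(out)
}

#' @rdname splice_ped
#' @param a,b Two [ped_dataset()] objects.
#' @export
splice_datasets <- function(a, b) {
  ids_a <- a$snps$snp_id
  ids_b <- b$snps$snp_id
  b_only <- setdiff(ids_b, ids_a)
  snp_ids <- c(ids_a, b_only)
  snps <- bind_rows(a$snps, b$snps[match(b_only, ids_b), , drop = FALSE])

  key <- function(s) do.call(paste, c(s, sep = "\r"))
  dup_b <- key(b$samples) %in% key(a$samples)
  keep_b <- which(!dup_b)

  n_out <- n_samples(a) + length(keep_b)
  geno <- matrix("00", n_out, length(snp_ids))
  pos_a <- match(ids_a, snp_ids)
  if (n_samples(a) && length(ids_a)) {
    geno[seq_len(n_samples(a)), pos_a] <- a$genotypes
  }
  pos_b <- match(ids_b, snp_ids)
  if (length(keep_b) && length(ids_b)) {
    geno[n_samples(a) + seq_along(keep_b), pos_b] <-
      b$genotypes[keep_b, , drop = FALSE]
  }
  samples <- bind_rows(a$samples, b$samples[keep_b, , drop = FALSE])
  out <- ped_dataset(samples, snps, geno)
  # a SNP must stay biallelic across the two sources
  allele_summary(out)
  out
}
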