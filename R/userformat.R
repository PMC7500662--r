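#' Expand a wildcard pattern into a series of labels
#'
#' Patterns drive generated row/column content in user-defined formats and
#' in [insert_rows_cols()].  Four wildcards are recognized: `#` (serial
#' numbers along the allele columns/rows), `$` (SNP serials), `@` (sample
#' serials) and `^ab` (the two characters `a`, `b` alternating along the
#' series).  `\#`, `\$`, `\@`, `\^` produce the literal character; `\,`
#' and `\t` produce a literal comma and tab.  A pattern containing no
#' unescaped wildcard expands to a single literal string.
#'
#' @param template The pattern string.
#' @param n Series length for wildcard expansion.
#' @param kind When given (`"allele"`, `"snp"` or `"sample"`), serial
#'   wildcards of a different kind raise a pattern error; `NULL` skips the
#'   check (plain file editing does not know marker semantics).
#' @return Character vector of length `n` (wildcards present) or 1
#'   (literal pattern).
#' @examples
#' expand_wildcard("A#", 3, kind = "allele")
#' expand_wildcard("A^ab", 3)
#' expand_wildcard("\\#tag", 5)
#' @export
expand_wildcard <- function(template, n, kind = NULL) {
  parts <- tokenize_pattern(template)
  has_wild <- any(vapply(parts, function(p) p$type != "lit", logical(1)))
  if (!has_wild) {
    return(paste(vapply(parts, `[[`, character(1), "text"), collapse = ""))
  }
  if (!is.null(kind)) {
    wild_kinds <- c("#" = "allele", "$" = "snp", "@" = "sample")
    for (p in parts) {
      if (p$type == "serial" && wild_kinds[[p$text]] != kind) {
        abort(sprintf("wildcard '%s' expands along the %s axis, not the %s axis",
                      p$text, wild_kinds[[p$text]], kind),
              class = "pedkit_pattern_error")
      }
    }
  }
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(vapply(parts, function(p) {
      switch(p$type,
             lit = p$text,
             serial = as.character(i),
             # two alternate characters cycling with period 2
             alt = if (i %% 2L == 1L) p$a else p$b)
    }, character(1)), collapse = "")
  }, character(1))
}

tokenize_pattern <- function(template) {
  chars <- strsplit(template, "", fixed = TRUE)[[1L]]
  parts <- list()
  i <- 1L
  lit <- character(0)
  flush <- function() {
    if (length(lit)) {
      parts[[length(parts) + 1L]] <<- list(type = "lit",
                                           text = paste(lit, collapse = ""))
      lit <<- character(0)
    }
  }
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "\\" && i < length(chars)) {
      nxt <- chars[[i + 1L]]
      lit <- c(lit, if (nxt == "t") "\t" else nxt)
      i <- i + 2L
    } else if (ch %in% c("#", "$", "@")) {
      flush()
      parts[[length(parts) + 1L]] <- list(type = "serial", text = ch)
      i <- i + 1L
    } else if (ch == "^") {
      if (i + 2L > length(chars)) {
        abort(sprintf("'^' in pattern '%s' must be followed by exactly two alternate characters",
                      template),
              class = "pedkit_pattern_error")
      }
      flush()
      parts[[length(parts) + 1L]] <- list(type = "alt",
                                          a = chars[[i + 1L]],
                                          b = chars[[i + 2L]])
      i <- i + 3L
    } else {
      lit <- c(lit, ch)
      i <- i + 1L
    }
  }
  flush()
  if (!length(parts)) parts <- list(list(type = "lit", text = ""))
  parts
}

# ---------------------------------------------------------------------------
# arguments-file grammar
#
# Line-oriented, three sections whose headers (MATRIX, VECTOR, INSERT) stand
# on their own line and are matched case-insensitively; '#'-initial lines
# are comments.  Items on a line are comma-delimited; '\,' and '\t' yield a
# literal comma/tab; trailing empty items are ignored.
#
#   MATRIX        exactly one section
#     file, K                output file carrying the matrix (default 1)
#     orientation, samples-as-rows | snps-as-rows
#     cell, split | fused    two delimited fields per call, or one "AC" field
#     delimiter, space | tab | comma [, K]   per-file delimiter (default space)
#   VECTOR        zero or more lines: name, position [, file]
#     sample fields: FamilyID IndividualID PaternalID MaternalID Sex Phenotype
#     marker fields: SNPID Chromosome Position Distance
#     Positions are 1-based counting all rows/columns of the emitted file;
#     a vector of per-sample fields runs along the sample axis (a column
#     when samples are rows), marker fields along the marker axis.  In a
#     file other than the matrix file every vector is a column.
#   INSERT        zero or more lines: [file,] row|col, position, item [, item...]
#     Each item is a wildcard pattern; serial items expand along the
#     perpendicular axis, literal items occupy one cell (a lone literal
#     column item is recycled down the column).
# ---------------------------------------------------------------------------

sample_field_names <- c(familyid = "family_id", fid = "family_id",
                        individualid = "individual_id", iid = "individual_id",
                        sampleid = "individual_id",
                        paternalid = "paternal_id", pid = "paternal_id",
                        maternalid = "maternal_id", mid = "maternal_id",
                        sex = "sex", phenotype = "phenotype",
                        pheno = "phenotype")
snp_field_names <- c(snpid = "snp_id", rs = "snp_id", markerid = "snp_id",
                     chromosome = "chrom", chrom = "chrom", chr = "chrom",
                     position = "bp", bp = "bp",
                     distance = "cm", cm = "cm")

split_items <- function(line) {
  # protect escaped commas, resolve '\t', split, trim, drop trailing empties
  line <- gsub("\\\\,", "\x01", line)
  line <- gsub("\\\\t", "\t", line)
  items <- trimws(strsplit(line, ",", fixed = TRUE)[[1L]])
  while (length(items) && !nzchar(items[[length(items)]])) {
    items <- items[-length(items)]
  }
  gsub("\x01", ",", items, fixed = TRUE)
}

#' Parse an arguments file describing a user-defined format
#'
#' @param text The arguments-file content, as a single string or a
#'   character vector of lines.
#' @return A `format_spec` object with elements `matrix` (file,
#'   orientation, cell layout), `delimiters` (per output file), `vectors`
#'   (tibble: field, position, file, kind) and `inserts` (tibble: file,
#'   axis, position, patterns).
#' @export
parse_arguments_file <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lines <- trimws(text)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    abort("empty arguments file", class = "pedkit_spec_error")
  }
  section <- NA_character_
  mat <- list(file = 1L, orientation = "samples-as-rows", cell = "split")
  delims <- c("1" = " ")
  seen_matrix <- FALSE
  vectors <- list()
  inserts <- list()
  for (ln in lines) {
    up <- toupper(ln)
    if (up %in% c("MATRIX", "VECTOR", "INSERT")) {
      section <- up
      if (up == "MATRIX") seen_matrix <- TRUE
      next
    }
    if (is.na(section)) {
      abort(sprintf("line before any section header: '%s'", ln),
            class = "pedkit_spec_error")
    }
    items <- split_items(ln)
    if (!length(items)) next
    if (section == "MATRIX") {
      key <- tolower(items[[1L]])
      if (key == "file") {
        mat$file <- as.integer(items[[2L]])
      } else if (key == "orientation") {
        val <- tolower(items[[2L]])
        if (!val %in% c("samples-as-rows", "snps-as-rows")) {
          abort(sprintf("unknown orientation '%s'", items[[2L]]),
                class = "pedkit_spec_error")
        }
        mat$orientation <- val
      } else if (key == "cell") {
        val <- tolower(items[[2L]])
        if (!val %in% c("split", "fused")) {
          abort(sprintf("unknown cell layout '%s'", items[[2L]]),
                class = "pedkit_spec_error")
        }
        mat$cell <- val
      } else if (key == "delimiter") {
        d <- switch(tolower(items[[2L]]),
                    space = " ", tab = "\t", comma = ",",
                    abort(sprintf("unknown delimiter '%s'", items[[2L]]),
                          class = "pedkit_spec_error"))
        k <- if (length(items) >= 3L) items[[3L]] else "1"
        delims[[k]] <- d
      } else {
        abort(sprintf("unknown MATRIX key '%s'", items[[1L]]),
              class = "pedkit_spec_error")
      }
    } else if (section == "VECTOR") {
      nm <- tolower(gsub("[ _]", "", items[[1L]]))
      kind <- if (nm %in% names(sample_field_names)) "sample"
              else if (nm %in% names(snp_field_names)) "snp"
              else abort(sprintf("unknown vector field '%s'", items[[1L]]),
                         class = "pedkit_spec_error")
      field <- if (kind == "sample") sample_field_names[[nm]] else
        snp_field_names[[nm]]
      if (length(items) < 2L) {
        abort(sprintf("vector '%s' is missing its position", items[[1L]]),
              class = "pedkit_spec_error")
      }
      vectors[[length(vectors) + 1L]] <- tibble(
        field = field, kind = kind,
        position = as.integer(items[[2L]]),
        file = if (length(items) >= 3L) as.integer(items[[3L]]) else 1L)
    } else {  # INSERT
      file_k <- 1L
      if (grepl("^[0-9]+$", items[[1L]])) {
        file_k <- as.integer(items[[1L]])
        items <- items[-1L]
      }
      axis <- tolower(items[[1L]])
      if (!axis %in% c("row", "col")) {
        abort(sprintf("INSERT axis must be 'row' or 'col', got '%s'", axis),
              class = "pedkit_spec_error")
      }
      if (length(items) < 3L) {
        abort("INSERT needs axis, position and at least one pattern",
              class = "pedkit_spec_error")
      }
      inserts[[length(inserts) + 1L]] <- tibble(
        file = file_k, axis = axis, position = as.integer(items[[2L]]),
        patterns = list(items[-(1:2)]))
    }
  }
  if (!seen_matrix) {
    abort("arguments file has no MATRIX section", class = "pedkit_spec_error")
  }
  vectors <- if (length(vectors)) bind_rows(vectors) else
    tibble(field = character(), kind = character(),
           position = integer(), file = integer())
  inserts <- if (length(inserts)) bind_rows(inserts) else
    tibble(file = integer(), axis = character(), position = integer(),
           patterns = list())
  spec <- structure(list(matrix = mat, delimiters = delims,
                         vectors = vectors, inserts = inserts),
                    class = "format_spec")
  validate_format_spec(spec)
  spec
}

validate_format_spec <- function(spec) {
  # position collisions within one file/axis are spec errors before any I/O
  vec_ax <- ifelse(spec$vectors$file == spec$matrix$file,
                   vector_axis(spec, spec$vectors$kind), "col")
  for (k in unique(c(spec$matrix$file, spec$vectors$file, spec$inserts$file))) {
    for (ax in c("row", "col")) {
      pos <- c(spec$vectors$position[spec$vectors$file == k & vec_ax == ax],
               spec$inserts$position[spec$inserts$file == k &
                                     spec$inserts$axis == ax])
      dup <- pos[duplicated(pos)]
      if (length(dup)) {
        abort(sprintf("position collision in file %d: %s %s declared twice",
                      k, ax, paste(unique(dup), collapse = ", ")),
              class = "pedkit_spec_error")
      }
    }
  }
  invisible(spec)
}

# which final-file axis a vector of the given kind occupies in the matrix
# file: sample-kind fields run along the sample axis
vector_axis <- function(spec, kind) {
  if (spec$matrix$orientation == "samples-as-rows") {
    ifelse(kind == "sample", "col", "row")
  } else {
    ifelse(kind == "sample", "row", "col")
  }
}

file_delim <- function(spec, k) {
  spec$delimiters[[as.character(k)]] %||% " "
}

#' Write a template arguments file
#'
#' When a conversion is requested with an absent arguments file, pedkit
#' writes a commented template illustrating the structure and meaning of
#' every argument, and aborts the conversion so the user can edit it.  The
#' emitted template itself parses cleanly with [parse_arguments_file()]
#' and is byte-identical across calls.
#'
#' @param path Destination; must not already exist.
#' @param direction `"ped2other"` or `"other2ped"` (content is the same
#'   grammar; the comment header states the direction).
#' @return Invisibly, the path.
#' @export
generate_template <- function(path, direction = c("ped2other", "other2ped")) {
  direction <- match.arg(direction)
  if (file.exists(path)) {
    abort(sprintf("refusing to overwrite existing arguments file: %s", path),
          class = "pedkit_io_error")
  }
  lines <- c(
    sprintf("# arguments-file template (%s)", direction),
    "# Items on a line are comma-delimited; '\\,' and '\\t' give a literal",
    "# comma/tab.  Trailing commas and empty items are ignored.",
    "# Wildcards in patterns: # = allele serials, $ = SNP serials,",
    "# @ = sample serials, ^ab = the characters a and b alternating;",
    "# \\# \\$ \\@ \\^ give the literal character.",
    "MATRIX",
    "# file carrying the genotype matrix (1 = first output/input file)",
    "file, 1",
    "# samples-as-rows or snps-as-rows",
    "orientation, samples-as-rows",
    "# split = two delimited fields per genotype, fused = one 'AC' field",
    "cell, split",
    "# delimiter, space|tab|comma [, file]",
    "delimiter, space",
    "VECTOR",
    "# field, position [, file]; positions are 1-based in the emitted file",
    "IndividualID, 1",
    "Phenotype, 2",
    "INSERT",
    "# [file,] row|col, position, item [, item ...]",
    "row, 1, ID, Pheno, A#"
  )
  write_text_lines(lines, path)
  invisible(path)
}

# span of the matrix block along rows/cols of the emitted matrix file
matrix_extent <- function(spec, n, m) {
  if (spec$matrix$orientation == "samples-as-rows") {
    list(rows = n, cols = if (spec$matrix$cell == "split") 2L * m else m,
         row_kind = "sample", col_kind = if (spec$matrix$cell == "split")
           "allele" else "snp")
  } else {
    list(rows = m, cols = if (spec$matrix$cell == "split") 2L * n else n,
         row_kind = "snp", col_kind = if (spec$matrix$cell == "split")
           "sample2" else "sample")
  }
}

kind_count <- function(kind, n, m) {
  switch(kind, sample = n, snp = m, allele = 2L * m, sample2 = 2L * n)
}

# expand one insert item list along an axis of `span` cells: serial items
# expand to their kind count, literals take one cell; a single literal
# item is recycled across the span (constant row/column)
expand_insert_items <- function(patterns, span, n, m, axis_kind) {
  expanded <- lapply(patterns, function(p) {
    parts <- tokenize_pattern(p)
    wild <- vapply(parts, function(x) x$type != "lit", logical(1))
    if (!any(wild)) return(expand_wildcard(p, 1L))
    serial <- vapply(parts, function(x) x$type == "serial", logical(1))
    count <- span
    if (any(serial)) {
      ch <- parts[serial][[1L]]$text
      count <- switch(ch, "#" = 2L * m, "$" = m, "@" = n)
    }
    expand_wildcard(p, count)
  })
  out <- unlist(expanded)
  if (length(patterns) == 1L && length(out) == 1L && span > 1L) {
    out <- rep(out, span)  # constant content
  }
  out
}

#' Convert a dataset to a user-defined format
#'
#' Lays the genotype matrix, pedigree/marker vectors and inserted
#' rows/columns out according to an arguments file.  Several output files
#' can be emitted in one call (for example a genotype matrix file plus a
#' marker list file).
#'
#' @param ds A [ped_dataset()].
#' @param spec A `format_spec` from [parse_arguments_file()], or the path
#'   of an arguments file.
#' @param paths Character vector of output paths, one per declared file
#'   index.
#' @return Invisibly, `paths`.
#' @export
ped_to_user <- function(ds, spec, paths) {
  spec <- as_format_spec(spec)
  n <- n_samples(ds); m <- n_snps(ds)
  ext <- matrix_extent(spec, n, m)
  n_files <- max(c(spec$matrix$file, spec$vectors$file, spec$inserts$file, 1L))
  if (length(paths) < n_files) {
    abort(sprintf("spec references file %d but only %d path(s) given",
                  n_files, length(paths)),
          class = "pedkit_spec_error")
  }
  for (k in seq_len(n_files)) {
    grid <- if (k == spec$matrix$file) {
      build_matrix_grid(ds, spec, ext)
    } else {
      build_vector_grid(ds, spec, k, n, m)
    }
    rows_out <- place_rows(grid, ds, spec, k, n, m, ext)
    write_text_lines(
      vapply(rows_out, paste, character(1), collapse = file_delim(spec, k)),
      paths[[k]])
  }
  invisible(paths)
}

# matrix block with vector/insert columns placed at absolute positions
build_matrix_grid <- function(ds, spec, ext) {
  n <- n_samples(ds); m <- n_snps(ds)
  block <- matrix_block(ds, spec)
  vecs <- spec$vectors[spec$vectors$file == spec$matrix$file &
                       vector_axis(spec, spec$vectors$kind) == "col", ,
                       drop = FALSE]
  ins <- spec$inserts[spec$inserts$file == spec$matrix$file &
                      spec$inserts$axis == "col", , drop = FALSE]
  extra_pos <- c(vecs$position, ins$position)
  total <- ncol(block) + length(extra_pos)
  if (length(extra_pos) && max(extra_pos) > total) {
    abort(sprintf("column position %d exceeds emitted width %d",
                  max(extra_pos), total),
          class = "pedkit_spec_error")
  }
  out <- matrix("", nrow(block), total)
  for (i in seq_len(nrow(vecs))) {
    out[, vecs$position[[i]]] <- vector_values(ds, spec, vecs$field[[i]],
                                               vecs$kind[[i]], nrow(block))
  }
  for (i in seq_len(nrow(ins))) {
    vals <- expand_insert_items(ins$patterns[[i]], nrow(block), n, m, "col")
    if (length(vals) != nrow(block)) {
      abort(sprintf("inserted column at position %d has %d value(s) for %d row(s)",
                    ins$position[[i]], length(vals), nrow(block)),
            class = "pedkit_spec_error")
    }
    out[, ins$position[[i]]] <- vals
  }
  out[, setdiff(seq_len(total), extra_pos)] <- block
  out
}

matrix_block <- function(ds, spec) {
  n <- n_samples(ds); m <- n_snps(ds)
  g <- if (spec$matrix$orientation == "samples-as-rows") ds$genotypes else
    t(ds$genotypes)
  if (spec$matrix$cell == "fused") return(g)
  out <- matrix("", nrow(g), 2L * ncol(g))
  if (length(g)) {
    out[, 2L * seq_len(ncol(g)) - 1L] <- substr(g, 1L, 1L)
    out[, 2L * seq_len(ncol(g))] <- substr(g, 2L, 2L)
  }
  out
}

# per-sample or per-snp values, doubled when running along split cells
vector_values <- function(ds, spec, field, kind, span) {
  vals <- if (kind == "sample") ds$samples[[field]] else {
    v <- ds$snps[[field]]
    if (field %in% c("cm", "bp")) format_num(v) else v
  }
  if (length(vals) * 2L == span) vals <- rep(vals, each = 2L)
  if (length(vals) != span) {
    abort(sprintf("vector '%s' has %d value(s) but the axis spans %d",
                  field, length(vals), span),
          class = "pedkit_spec_error")
  }
  vals
}

# secondary (vector-only) file: every vector is a column
build_vector_grid <- function(ds, spec, k, n, m) {
  vecs <- spec$vectors[spec$vectors$file == k, , drop = FALSE]
  if (!nrow(vecs)) {
    abort(sprintf("file %d has neither matrix nor vectors", k),
          class = "pedkit_spec_error")
  }
  lens <- ifelse(vecs$kind == "sample", n, m)
  if (length(unique(lens)) > 1L) {
    abort(sprintf("file %d mixes sample-length and SNP-length vectors", k),
          class = "pedkit_spec_error")
  }
  total <- nrow(vecs) +
    sum(spec$inserts$file == k & spec$inserts$axis == "col")
  out <- matrix("", lens[[1L]], total)
  for (i in seq_len(nrow(vecs))) {
    out[, vecs$position[[i]]] <- vector_values(ds, spec, vecs$field[[i]],
                                               vecs$kind[[i]], lens[[1L]])
  }
  ins <- spec$inserts[spec$inserts$file == k & spec$inserts$axis == "col", ,
                      drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    vals <- expand_insert_items(ins$patterns[[i]], lens[[1L]], n, m, "col")
    if (length(vals) == 1L) vals <- rep(vals, lens[[1L]])
    out[, ins$position[[i]]] <- vals
  }
  out
}

# interleave body rows with vector rows and inserted rows at their
# absolute 1-based positions
place_rows <- function(grid, ds, spec, k, n, m, ext) {
  body <- lapply(seq_len(nrow(grid)), function(i) grid[i, ])
  extras <- list()
  if (k == spec$matrix$file) {
    vecs <- spec$vectors[spec$vectors$file == k &
                         vector_axis(spec, spec$vectors$kind) == "row", ,
                         drop = FALSE]
    mat_cols <- setdiff(seq_len(ncol(grid)), extra_col_positions(spec, k))
    for (i in seq_len(nrow(vecs))) {
      # cells of a vector row above extra columns carry the field key as a
      # label; the importer skips those positions
      row_vals <- rep(vecs$field[[i]], ncol(grid))
      core <- vector_values(ds, spec, vecs$field[[i]], vecs$kind[[i]],
                            length(mat_cols))
      row_vals[mat_cols] <- core
      extras[[length(extras) + 1L]] <- list(pos = vecs$position[[i]],
                                            vals = row_vals)
    }
  }
  ins <- spec$inserts[spec$inserts$file == k & spec$inserts$axis == "row", ,
                      drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    extras[[length(extras) + 1L]] <- list(
      pos = ins$position[[i]],
      vals = expand_insert_items(ins$patterns[[i]], ncol(grid), n, m, "row"))
  }
  total <- length(body) + length(extras)
  pos <- vapply(extras, function(e) e$pos, integer(1))
  if (length(pos) && max(pos) > total) {
    abort(sprintf("row position %d exceeds emitted height %d",
                  max(pos), total),
          class = "pedkit_spec_error")
  }
  out <- vector("list", total)
  for (e in extras) out[[e$pos]] <- e$vals
  body_slots <- setdiff(seq_len(total), pos)
  for (i in seq_along(body)) out[[body_slots[[i]]]] <- body[[i]]
  out
}

# column positions occupied by vectors/inserts in file k
extra_col_positions <- function(spec, k) {
  vec_pos <- if (k == spec$matrix$file) {
    spec$vectors$position[spec$vectors$file == k &
                          vector_axis(spec, spec$vectors$kind) == "col"]
  } else {
    spec$vectors$position[spec$vectors$file == k]
  }
  sort(c(vec_pos,
         spec$inserts$position[spec$inserts$file == k &
                               spec$inserts$axis == "col"]))
}

extra_row_positions <- function(spec, k) {
  vec_pos <- if (k == spec$matrix$file) {
    spec$vectors$position[spec$vectors$file == k &
                          vector_axis(spec, spec$vectors$kind) == "row"]
  } else {
    integer(0)
  }
  sort(c(vec_pos,
         spec$inserts$position[spec$inserts$file == k &
                               spec$inserts$axis == "row"]))
}

split_user_lines <- function(path, delim) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (delim == " ") ws_split(lines) else strsplit(lines, delim, fixed = TRUE)
}

# undouble a vector running along split cells (take the first allele column
# of each pair)
undouble <- function(vals, split_cells) {
  if (split_cells) vals[seq(1L, length(vals), by = 2L)] else vals
}

#' Read a user-defined format back into a dataset
#'
#' Inverse of [ped_to_user()]: vectors populate the pedigree/marker
#' columns they are mapped to, unmapped columns default to `0`, inserted
#' rows/columns are skipped, and matrix cells are parsed into genotype
#' calls per the declared cell layout.
#'
#' @param paths Character vector of input paths, one per declared file
#'   index.
#' @param spec A `format_spec` from [parse_arguments_file()], or the path
#'   of an arguments file.
#' @return A [ped_dataset()].
#' @export
user_to_ped <- function(paths, spec) {
  spec <- as_format_spec(spec)
  k0 <- spec$matrix$file
  n_files <- max(c(k0, spec$vectors$file, spec$inserts$file, 1L))
  if (length(paths) < n_files) {
    abort(sprintf("spec references file %d but only %d path(s) given",
                  n_files, length(paths)),
          class = "pedkit_spec_error")
  }
  split_cells <- spec$matrix$cell == "split"
  samples_as_rows <- spec$matrix$orientation == "samples-as-rows"

  fields <- split_user_lines(paths[[k0]], file_delim(spec, k0))
  row_pos <- extra_row_positions(spec, k0)
  if (length(row_pos) && max(row_pos) > length(fields)) {
    abort(sprintf("file %d has %d row(s) but the spec declares content at row %d",
                  k0, length(fields), max(row_pos)),
          class = "pedkit_structure_error")
  }
  body_slots <- setdiff(seq_along(fields), row_pos)
  body <- fields[body_slots]
  if (!length(body)) {
    abort("matrix file has no body rows", class = "pedkit_structure_error")
  }
  width <- assert_rectangular(body, "matrix body")
  col_pos <- extra_col_positions(spec, k0)
  if (length(col_pos) && max(col_pos) > width) {
    abort(sprintf("spec declares a column at %d but rows have %d field(s)",
                  max(col_pos), width),
          class = "pedkit_structure_error")
  }
  mat_cols <- setdiff(seq_len(width), col_pos)
  body_mat <- matrix(unlist(body), nrow = length(body), byrow = TRUE)
  block <- body_mat[, mat_cols, drop = FALSE]

  C <- ncol(block)
  if (split_cells && C %% 2L != 0L) {
    abort(sprintf("matrix block has %d column(s); split cells need an even count",
                  C),
          class = "pedkit_structure_error")
  }
  if (samples_as_rows) {
    n <- nrow(block); m <- if (split_cells) C %/% 2L else C
  } else {
    m <- nrow(block); n <- if (split_cells) C %/% 2L else C
  }

  samples <- tibble(family_id = rep("0", n), individual_id = rep("0", n),
                    paternal_id = rep("0", n), maternal_id = rep("0", n),
                    sex = rep("0", n), phenotype = rep("0", n))
  samples$individual_id <- paste0("I", seq_len(n))
  snps <- tibble(chrom = rep("0", m), snp_id = paste0("snp_", seq_len(m)),
                 cm = rep(0, m), bp = rep(0, m))

  assign_field <- function(field, kind, vals) {
    expect <- if (kind == "sample") n else m
    if (length(vals) != expect) {
      abort(sprintf("vector '%s' has %d value(s) but the dataset has %d %s(s)",
                    field, length(vals), expect, kind),
            class = "pedkit_structure_error")
    }
    if (kind == "sample") {
      samples[[field]] <<- vals
    } else if (field %in% c("cm", "bp")) {
      snps[[field]] <<- as.numeric(vals)
    } else {
      snps[[field]] <<- vals
    }
  }

  # vectors in the matrix file
  vecs0 <- spec$vectors[spec$vectors$file == k0, , drop = FALSE]
  for (i in seq_len(nrow(vecs0))) {
    ax <- vector_axis(spec, vecs0$kind[[i]])
    if (ax == "col") {
      vals <- body_mat[, vecs0$position[[i]]]
    } else {
      row_vals <- fields[[vecs0$position[[i]]]]
      if (length(row_vals) != width) {
        abort(sprintf("vector row %d has %d field(s); body rows have %d",
                      vecs0$position[[i]], length(row_vals), width),
              class = "pedkit_structure_error")
      }
      vals <- undouble(row_vals[mat_cols], split_cells)
    }
    assign_field(vecs0$field[[i]], vecs0$kind[[i]], vals)
  }

  # vectors in secondary files (always columns there)
  for (k in setdiff(seq_len(n_files), k0)) {
    vecs <- spec$vectors[spec$vectors$file == k, , drop = FALSE]
    if (!nrow(vecs)) next
    f2 <- split_user_lines(paths[[k]], file_delim(spec, k))
    rp <- extra_row_positions(spec, k)
    f2 <- f2[setdiff(seq_along(f2), rp)]
    w2 <- assert_rectangular(f2, sprintf("file %d", k))
    if (length(f2) && w2 < max(vecs$position)) {
      abort(sprintf("file %d rows have %d field(s) but a vector sits at column %d",
                    k, w2, max(vecs$position)),
            class = "pedkit_structure_error")
    }
    m2 <- matrix(unlist(f2), nrow = length(f2), byrow = TRUE)
    for (i in seq_len(nrow(vecs))) {
      assign_field(vecs$field[[i]], vecs$kind[[i]], m2[, vecs$position[[i]]])
    }
  }

  geno <- if (split_cells) {
    a1 <- block[, seq(1L, C, by = 2L), drop = FALSE]
    a2 <- block[, seq(2L, C, by = 2L), drop = FALSE]
    if (length(a1) && any(nchar(c(a1, a2)) != 1L)) {
      a1[] <- reduce_allele(a1)
      a2[] <- reduce_allele(a2)
    }
    g <- paste0(a1, a2); dim(g) <- dim(a1); g
  } else {
    if (length(block) && any(nchar(block) != 2L)) {
      bad <- block[nchar(block) != 2L][[1L]]
      abort(sprintf("fused genotype cell '%s' is not two characters", bad),
            class = "pedkit_parse_error")
    }
    block
  }
  if (!samples_as_rows) geno <- t(geno)
  ped_dataset(samples, snps, geno)
}

as_format_spec <- function(spec) {
  if (inherits(spec, "format_spec")) return(spec)
  parse_arguments_file(read_text_lines(spec))
}
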