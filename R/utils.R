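# internal helpers shared across modules

# collapse runs of spaces/tabs and strip leading/trailing ones;
# this is the whitespace normalization applied before text comparison
collapse_ws <- function(x) {
  gsub("[ \t]+", " ", trimws(x, whitespace = "[ \t]"))
}

# split lines on runs of whitespace; blank lines give character(0)
ws_split <- function(lines) {
  out <- strsplit(collapse_ws(lines), " ", fixed = TRUE)
  lapply(out, function(f) f[nzchar(f)])
}

read_text_lines <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "pedkit_io_error")
  }
  readLines(path, warn = FALSE)
}

write_text_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

# rows of a character matrix pasted with a single-character delimiter
paste_rows <- function(mat, sep = " ") {
  if (nrow(mat) == 0L) return(character(0))
  if (ncol(mat) == 0L) return(rep("", nrow(mat)))
  do.call(paste, c(split(mat, col(mat)), sep = sep))
}

# rectangularity check for a list of field vectors; returns field count
assert_rectangular <- function(fields, what = "input") {
  widths <- lengths(fields)
  if (length(widths) == 0L) return(0L)
  bad <- which(widths != widths[[1L]])
  if (length(bad)) {
    abort(sprintf("%s is ragged: row %d has %d fields, row 1 has %d",
                  what, bad[[1L]], widths[[bad[[1L]]]], widths[[1L]]),
          class = "pedkit_parse_error")
  }
  widths[[1L]]
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# detect NUL bytes in the head of a file (binary vs text comparison)
looks_binary <- function(path, n = 8192L) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = min(n, sz))
  any(raw == as.raw(0L))
}
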