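#' Convert between space-delimited text and CSV
#'
#' In the `"to-csv"` direction, runs of whitespace become single commas
#' and fields containing a comma or a double quote are quoted RFC-4180
#' style.  In the `"to-space"` direction, CSV fields (honouring quoting)
#' become single-space-delimited fields; a field containing a space cannot
#' be represented and is rejected with an error.  A round trip restores
#' the original up to whitespace collapsing.  Ragged rows are allowed and
#' pass through with a warning, keeping their own length.
#'
#' @param path_in,path_out Input and output paths.
#' @param direction `"to-csv"` or `"to-space"`.
#' @return Invisibly, the output path.
#' @export
csv_space_convert <- function(path_in, path_out,
                              direction = c("to-csv", "to-space")) {
  direction <- match.arg(direction)
  lines <- read_text_lines(path_in)
  if (direction == "to-csv") {
    fields <- ws_split(lines)
    warn_ragged(fields)
    out <- vapply(fields, function(f) {
      needs <- grepl("[,\"]", f)
      f[needs] <- paste0('"', gsub('"', '""', f[needs]), '"')
      paste(f, collapse = ",")
    }, character(1))
  } else {
    fields <- lapply(lines, parse_csv_line)
    warn_ragged(fields)
    out <- vapply(fields, function(f) {
      bad <- grepl("[ \t]", f)
      if (any(bad)) {
        abort(sprintf(
          "field '%s' contains whitespace and cannot be space-delimited",
          f[bad][[1L]]),
          class = "pedkit_export_error")
      }
      paste(f, collapse = " ")
    }, character(1))
  }
  write_text_lines(out, path_out)
  invisible(path_out)
}

warn_ragged <- function(fields) {
  widths <- unique(lengths(fields))
  if (length(widths) > 1L) {
    warn(sprintf("ragged input: row widths %s; passing rows through unchanged",
                 paste(sort(widths), collapse = ", ")))
  }
}

# minimal RFC-4180 field scanner for one line
parse_csv_line <- function(line) {
  if (!nzchar(line)) return(character(0))
  out <- scan(text = line, what = character(), sep = ",", quote = '"',
              quiet = TRUE, blank.lines.skip = FALSE, strip.white = FALSE)
  out
}
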