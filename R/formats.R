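#' Genotype codings shared by the numeric export formats
#'
#' `code_additive()` counts minor alleles: homozygous-major 0,
#' heterozygous 1, homozygous-minor 2, missing 3 (substituted by a
#' format's own missing code at write time).  `code_letter_order()`
#' numbers the three genotype classes alphabetically by their sorted
#' two-letter string (AA < AC < CC), irrespective of which allele is
#' major.  The two codings coincide on every call exactly when the major
#' allele sorts first alphabetically.
#'
#' @param calls Character vector of two-character genotype calls.
#' @param major,minor Single allele characters from [allele_summary()].
#' @return Integer vector of codes.
#' @examples
#' code_additive(c("AA", "AC", "CC", "00"), major = "A", minor = "C")
#' code_letter_order(c("AA", "AC", "CC"), major = "C", minor = "A")
#' @export
code_additive <- function(calls, major, minor) {
  a1 <- substr(calls, 1L, 1L)
  a2 <- substr(calls, 2L, 2L)
  miss <- is_missing_char(a1) | is_missing_char(a2)
  ok <- miss | (a1 %in% c(major, minor) & a2 %in% c(major, minor))
  if (!all(ok)) {
    abort(sprintf("allele outside {%s, %s} in call '%s'", major, minor,
                  calls[!ok][[1L]]),
          class = "pedkit_internal_error")
  }
  out <- (a1 != major) + (a2 != major)
  out[miss] <- 3L
  as.integer(out)
}

#' @rdname code_additive
#' @export
code_letter_order <- function(calls, major, minor) {
  g <- code_additive(calls, major, minor)
  # class order is alphabetical on the sorted pair; when the major allele
  # sorts later, additive order is reversed
  if (minor != "0" && utf8ToInt(minor) < utf8ToInt(major)) {
    out <- ifelse(g == 3L, 3L, 2L - g)
  } else {
    out <- g
  }
  as.integer(out)
}

# ---------------------------------------------------------------------------
# registry of built-in third-party dialects
# ---------------------------------------------------------------------------

format_defs <- function() {
  list(
    beam = list(orientation = "snps-as-rows", coding = "additive",
                delimiter = " ", missing_code = "3",
                header = "status-row", phenotype = "header-row",
                importer = TRUE,
                description = "marker rows (id chrom bp) after a case/control status row"),
    boost = list(orientation = "samples-as-rows", coding = "additive",
                 delimiter = " ", missing_code = "3",
                 header = "none", phenotype = "first-column",
                 importer = TRUE,
                 description = "class label first, then additive codes"),
    mdr = list(orientation = "samples-as-rows", coding = "additive",
               delimiter = "\t", missing_code = "-1",
               header = "snp-names", phenotype = "last-column",
               importer = TRUE,
               description = "tab-delimited, SNP-name header plus Class column"),
    svmsnps = list(orientation = "samples-as-rows", coding = "additive",
                   delimiter = " ", missing_code = "3",
                   header = "none", phenotype = "last-column",
                   importer = TRUE,
                   description = "numeric matrix with trailing label; indicator coding = additive|letter"),
    me = list(orientation = "samples-as-rows", coding = "additive",
              delimiter = " ", missing_code = "3",
              header = "none", phenotype = "first-column",
              importer = TRUE,
              description = "additive-coded sample-row matrix, class first"),
    logicreg = list(orientation = "samples-as-rows", coding = "additive",
                    delimiter = " ", missing_code = "3",
                    header = "none", phenotype = "first-column",
                    importer = FALSE,
                    description = "model-recoded predictors (dominant/recessive/additive, logited or not)"),
    prettybase = list(orientation = "long", coding = "raw-alleles",
                      delimiter = "\t", missing_code = "N",
                      header = "none", phenotype = "none",
                      importer = TRUE,
                      description = "one line per sample-site pair; Slider and SeattleSNPs dialects"),
    geo = list(orientation = "snps-as-rows", coding = "raw-alleles",
               delimiter = "\t", missing_code = "NC",
               header = "sample-ids", phenotype = "none",
               importer = TRUE,
               description = "marker-by-sample matrix of two-letter calls, NC for no-call"),
    linkage = list(orientation = "samples-as-rows", coding = "raw-alleles",
                   delimiter = " ", missing_code = "0",
                   header = "none", phenotype = "sixth-column",
                   importer = TRUE,
                   description = "pre-makeped pedigree rows (PED without a MAP)"),
    gslinkage = list(orientation = "samples-as-rows", coding = "raw-alleles",
                     delimiter = " ", missing_code = "0",
                     header = "snp-names", phenotype = "sixth-column",
                     importer = TRUE,
                     description = "linkage rows preceded by a marker-name header row")
  )
}

#' Registry of built-in third-party formats
#'
#' One registered descriptor per supported dialect; the registry is the
#' single dispatch point for [export_dataset()] and [import_dataset()].
#'
#' @return A tibble with one row per format: `format`, `orientation`,
#'   `coding`, `delimiter`, `missing_code`, `header`, `phenotype`,
#'   `importer`, `description`.
#' @export
format_registry <- function() {
  defs <- format_defs()
  bind_rows(lapply(names(defs), function(id) {
    d <- defs[[id]]
    tibble(format = id, orientation = d$orientation, coding = d$coding,
           delimiter = if (d$delimiter == "\t") "tab" else "space",
           missing_code = d$missing_code, header = d$header,
           phenotype = d$phenotype, importer = d$importer,
           description = d$description)
  }))
}

get_format <- function(format) {
  defs <- format_defs()
  if (!format %in% names(defs)) {
    abort(sprintf("unknown format '%s'; see format_registry()", format),
          class = "pedkit_config_error")
  }
  defs[[format]]
}

check_indicators <- function(format, indicators, allowed) {
  bad <- setdiff(names(indicators), allowed)
  if (length(bad)) {
    abort(sprintf("unknown indicator(s) for format '%s': %s", format,
                  paste(bad, collapse = ", ")),
          class = "pedkit_config_error")
  }
}

# class/phenotype 1->0 (control), 2->1 (case); anything else is an error
# because these formats only represent binary status
pheno_to_class <- function(phenotype, format) {
  if (!all(phenotype %in% c("1", "2"))) {
    abort(sprintf(
      "format '%s' requires case/control phenotypes coded 1/2; found: %s",
      format, paste(head(setdiff(unique(phenotype), c("1", "2")), 3),
                    collapse = ", ")),
      class = "pedkit_export_error")
  }
  as.integer(phenotype == "2")
}

class_to_pheno <- function(class_col, format) {
  if (!all(class_col %in% c("0", "1"))) {
    abort(sprintf("class labels in '%s' input must be 0/1; found: %s",
                  format, paste(head(setdiff(unique(class_col), c("0", "1")), 3),
                                collapse = ", ")),
      class = "pedkit_parse_error")
  }
  ifelse(class_col == "1", "2", "1")
}

coded_matrix <- function(ds, coding = "additive", missing_code = "3") {
  summ <- allele_summary(ds)
  fn <- if (coding == "letter") code_letter_order else code_additive
  out <- matrix("", n_samples(ds), n_snps(ds))
  for (j in seq_len(n_snps(ds))) {
    g <- fn(ds$genotypes[, j], summ$major[[j]], summ$minor[[j]])
    out[, j] <- ifelse(g == 3L, missing_code, as.character(g))
  }
  out
}

# lift a numeric code matrix back to two-letter calls on the D/d alphabet;
# original letters are information-theoretically unrecoverable from codes
lift_coded <- function(code_mat, missing_code, coding = "additive",
                       format = "?") {
  n <- nrow(code_mat); m <- ncol(code_mat)
  geno <- matrix("NN", n, m)
  for (j in seq_len(m)) {
    x <- code_mat[, j]
    miss <- x == missing_code
    bad <- !miss & !x %in% c("0", "1", "2")
    if (any(bad)) {
      abort(sprintf("invalid genotype code '%s' in %s input (column %d)",
                    x[bad][[1L]], format, j),
            class = "pedkit_parse_error")
    }
    g <- suppressWarnings(as.integer(x))
    g[miss] <- 0L  # placeholder; overwritten below
    if (coding == "letter") {
      # class 0 is homozygous for the alphabetically first allele; recover
      # which class is major from the allele counts themselves
      n_a <- 2L * sum(g == 0L, na.rm = TRUE) + sum(g == 1L, na.rm = TRUE)
      n_b <- 2L * sum(g == 2L, na.rm = TRUE) + sum(g == 1L, na.rm = TRUE)
      # on a tie the alphabetically first allele is the major, matching the
      # ASCII tie-break used everywhere else
      calls <- if (n_a >= n_b) c("DD", "Dd", "dd") else c("dd", "dD", "DD")
    } else {
      calls <- c("DD", "Dd", "dd")
    }
    col <- calls[g + 1L]
    col[miss] <- "NN"
    geno[, j] <- col
  }
  geno
}

placeholder_samples <- function(n, phenotype = rep("0", n)) {
  tibble(family_id = paste0("F", seq_len(n)),
         individual_id = paste0("I", seq_len(n)),
         paternal_id = rep("0", n), maternal_id = rep("0", n),
         sex = rep("0", n), phenotype = phenotype)
}

placeholder_snps <- function(ids) {
  m <- length(ids)
  tibble(chrom = rep("0", m), snp_id = ids, cm = rep(0, m), bp = rep(0, m))
}

#' Export a dataset to a registered third-party format
#'
#' Output is deterministic: the same dataset always produces identical
#' bytes.  Case/control formats require phenotypes coded 1/2.
#'
#' @param ds A [ped_dataset()].
#' @param format A format id from [format_registry()].
#' @param path Output path (PrettyBase and GEO write a single file; so do
#'   all others).
#' @param indicators Named list of sub-format options, e.g.
#'   `list(coding = "letter")` for SVMSNPs, `list(version = "slider")` for
#'   PrettyBase, `list(model = "dominant", logited = TRUE)` for LogicReg.
#'   Unknown indicator names are rejected before any I/O.
#' @return Invisibly, the output path.
#' @export
export_dataset <- function(ds, format, path, indicators = list()) {
  def <- get_format(format)
  switch(format,
    mdr = {
      check_indicators(format, indicators, character())
      cls <- pheno_to_class(ds$samples$phenotype, format)
      codes <- coded_matrix(ds, "additive", def$missing_code)
      lines <- c(paste(c(ds$snps$snp_id, "Class"), collapse = "\t"),
                 paste_rows(cbind(codes, as.character(cls)), sep = "\t"))
      write_text_lines(lines, path)
    },
    boost = {
      check_indicators(format, indicators, character())
      cls <- pheno_to_class(ds$samples$phenotype, format)
      codes <- coded_matrix(ds, "additive", def$missing_code)
      write_text_lines(paste_rows(cbind(as.character(cls), codes)), path)
    },
    beam = {
      check_indicators(format, indicators, character())
      cls <- pheno_to_class(ds$samples$phenotype, format)
      codes <- coded_matrix(ds, "additive", def$missing_code)
      header <- paste(c("ID", "Chr", "Pos", as.character(cls)), collapse = " ")
      body <- paste_rows(cbind(ds$snps$snp_id, ds$snps$chrom,
                               format_num(ds$snps$bp), t(codes)))
      write_text_lines(c(header, body), path)
    },
    svmsnps = {
      check_indicators(format, indicators, "coding")
      coding <- indicators$coding %||% "additive"
      if (!coding %in% c("additive", "letter")) {
        abort("svmsnps indicator 'coding' must be 'additive' or 'letter'",
              class = "pedkit_config_error")
      }
      cls <- pheno_to_class(ds$samples$phenotype, format)
      codes <- coded_matrix(ds, coding, def$missing_code)
      write_text_lines(paste_rows(cbind(codes, as.character(cls))), path)
    },
    me = {
      check_indicators(format, indicators, character())
      cls <- pheno_to_class(ds$samples$phenotype, format)
      codes <- coded_matrix(ds, "additive", def$missing_code)
      write_text_lines(paste_rows(cbind(as.character(cls), codes)), path)
    },
    logicreg = export_logicreg(ds, path,
                               model = indicators$model %||% "additive",
                               logited = isTRUE(indicators$logited)),
    prettybase = {
      check_indicators(format, indicators, "version")
      version <- indicators$version %||% "seattlesnps"
      write_prettybase(ds, path, version)
    },
    geo = {
      check_indicators(format, indicators, character())
      calls <- ds$genotypes
      calls[is_missing_call(calls)] <- "NC"
      lines <- c(paste(c("ID_REF", ds$samples$individual_id), collapse = "\t"),
                 paste_rows(cbind(ds$snps$snp_id, t(calls)), sep = "\t"))
      write_text_lines(lines, path)
    },
    linkage = {
      check_indicators(format, indicators, character())
      write_text_lines(ped_lines(ds), path)
    },
    gslinkage = {
      check_indicators(format, indicators, character())
      header <- paste(c("FID", "IID", "PID", "MID", "SEX", "PHENO",
                        ds$snps$snp_id), collapse = " ")
      write_text_lines(c(header, ped_lines(ds)), path)
    }
  )
  invisible(path)
}

#' Export to logic-regression input
#'
#' Per SNP the additive minor-allele count `g` in \{0, 1, 2\} is recoded
#' under the chosen genetic model: dominant `1` if `g >= 1`, recessive `1`
#' if `g == 2`, additive `g` unchanged.  The phenotype column is written
#' first, as-is (non-logited) or mapped to 0/1 (logited; requires a binary
#' 1/2 phenotype).  Three models times two phenotype treatments give the
#' six supported combinations.
#'
#' @param ds A [ped_dataset()].
#' @param path Output path.
#' @param model `"dominant"`, `"recessive"` or `"additive"`.
#' @param logited Map the phenotype to 0/1 for a logistic response.
#' @return Invisibly, the output path.
#' @export
export_logicreg <- function(ds, path, model = "additive", logited = FALSE) {
  if (!model %in% c("dominant", "recessive", "additive")) {
    abort("model must be dominant, recessive or additive",
          class = "pedkit_config_error")
  }
  pheno <- if (logited) {
    as.character(pheno_to_class(ds$samples$phenotype, "logicreg"))
  } else {
    ds$samples$phenotype
  }
  codes <- coded_matrix(ds, "additive", "3")
  num <- suppressWarnings(matrix(as.integer(codes), nrow(codes), ncol(codes)))
  recoded <- switch(model,
    dominant = ifelse(num >= 1L & num != 3L, 1L, ifelse(num == 3L, 3L, 0L)),
    recessive = ifelse(num == 2L, 1L, ifelse(num == 3L, 3L, 0L)),
    additive = num)
  out <- matrix(as.character(recoded), nrow(codes), ncol(codes))
  write_text_lines(paste_rows(cbind(pheno, out)), path)
  invisible(path)
}

write_prettybase <- function(ds, path, version = "seattlesnps") {
  if (!version %in% c("seattlesnps", "slider")) {
    abort("prettybase version must be 'seattlesnps' or 'slider'",
          class = "pedkit_config_error")
  }
  delim <- if (version == "seattlesnps") "\t" else " "
  n <- n_samples(ds); m <- n_snps(ds)
  # one data line per sample-site pair, sites varying slowest
  site <- rep(ds$snps$snp_id, each = n)
  samp <- rep(ds$samples$individual_id, times = m)
  a1 <- substr(as.vector(ds$genotypes), 1L, 1L)
  a2 <- substr(as.vector(ds$genotypes), 2L, 2L)
  a1[is_missing_char(a1)] <- "N"
  a2[is_missing_char(a2)] <- "N"
  write_text_lines(paste(site, samp, a1, a2, sep = delim), path)
  invisible(path)
}

#' Detect the PrettyBase dialect of a file
#'
#' The SeattleSNPs dialect is tab-delimited with four fields per line; the
#' Slider dialect is the space-delimited variant.  The decision is made
#' from the first data line's delimiter/field signature.
#'
#' @param path Path to a PrettyBase file.
#' @return `"seattlesnps"` or `"slider"`.
#' @export
detect_prettybase_version <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort(sprintf("cannot identify PrettyBase dialect: %s has no data lines",
                  path),
          class = "pedkit_parse_error")
  }
  first <- lines[[1L]]
  if (length(strsplit(first, "\t", fixed = TRUE)[[1L]]) == 4L) {
    return("seattlesnps")
  }
  if (length(strsplit(collapse_ws(first), " ", fixed = TRUE)[[1L]]) == 4L) {
    return("slider")
  }
  abort(sprintf("unrecognized PrettyBase dialect in %s: first line matches neither signature",
                path),
        class = "pedkit_parse_error")
}

#' Import a registered third-party format
#'
#' Numeric codings are lifted back to two-letter genotypes on the
#' synthetic `D`/`d` (major/minor) alphabet, since the original allele
#' letters are not recoverable from codes; raw-allele formats (PrettyBase,
#' GEO, linkage) restore the original letters.  Pedigree fields a format
#' does not carry default to `0`.
#'
#' @param path Input path.
#' @param format A format id from [format_registry()].
#' @param indicators Named list of sub-format options (see
#'   [export_dataset()]); PrettyBase auto-detects its dialect.
#' @return A [ped_dataset()].
#' @export
import_dataset <- function(path, format, indicators = list()) {
  def <- get_format(format)
  if (!def$importer) {
    abort(sprintf("format '%s' is export-only", format),
          class = "pedkit_config_error")
  }
  switch(format,
    mdr = {
      fields <- split_nonblank(path, "\t")
      assert_rectangular(fields, "MDR input")
      header <- fields[[1L]]
      if (tail(header, 1L) != "Class") {
        abort("MDR input must end with a 'Class' header column",
              class = "pedkit_parse_error")
      }
      m <- length(header) - 1L
      body <- fields[-1L]
      mat <- body_matrix(body, m + 1L)
      geno <- lift_coded(mat[, seq_len(m), drop = FALSE], def$missing_code,
                         format = "MDR")
      ped_dataset(placeholder_samples(nrow(mat),
                                      class_to_pheno(mat[, m + 1L], format)),
                  placeholder_snps(head(header, m)), geno)
    },
    boost = , me = {
      fields <- split_nonblank(path, NULL)
      w <- assert_rectangular(fields, paste(format, "input"))
      mat <- body_matrix(fields, w)
      geno <- lift_coded(mat[, -1L, drop = FALSE], def$missing_code,
                         format = format)
      ped_dataset(placeholder_samples(nrow(mat),
                                      class_to_pheno(mat[, 1L], format)),
                  placeholder_snps(paste0("snp_", seq_len(w - 1L))), geno)
    },
    svmsnps = {
      check_indicators(format, indicators, "coding")
      coding <- indicators$coding %||% "additive"
      fields <- split_nonblank(path, NULL)
      w <- assert_rectangular(fields, "SVMSNPs input")
      mat <- body_matrix(fields, w)
      geno <- lift_coded(mat[, -w, drop = FALSE], def$missing_code,
                         coding = coding, format = "SVMSNPs")
      ped_dataset(placeholder_samples(nrow(mat),
                                      class_to_pheno(mat[, w], format)),
                  placeholder_snps(paste0("snp_", seq_len(w - 1L))), geno)
    },
    beam = {
      fields <- split_nonblank(path, NULL)
      assert_rectangular(fields, "BEAM input")
      header <- fields[[1L]]
      n <- length(header) - 3L
      cls <- class_to_pheno(header[-(1:3)], format)
      body <- fields[-1L]
      mat <- body_matrix(body, n + 3L)
      # lift_coded works column-wise on a sample-major matrix
      geno_sm <- lift_coded(t(mat[, -(1:3), drop = FALSE]), def$missing_code,
                            format = "BEAM")
      snps <- tibble(chrom = mat[, 2L], snp_id = mat[, 1L],
                     cm = rep(0, nrow(mat)), bp = as.numeric(mat[, 3L]))
      ped_dataset(placeholder_samples(n, cls), snps, geno_sm)
    },
    prettybase = {
      version <- indicators$version %||% detect_prettybase_version(path)
      inform(sprintf("PrettyBase dialect: %s", version))
      delim <- if (version == "seattlesnps") "\t" else NULL
      fields <- split_nonblank(path, delim)
      bad <- which(lengths(fields) != 4L)
      if (length(bad)) {
        abort(sprintf("PrettyBase line %d has %d field(s); expected 4",
                      bad[[1L]], length(fields[[bad[[1L]]]])),
              class = "pedkit_parse_error")
      }
      mat <- body_matrix(fields, 4L)
      sites <- unique(mat[, 1L])
      samps <- unique(mat[, 2L])
      geno <- matrix("00", length(samps), length(sites),
                     dimnames = list(samps, sites))
      a1 <- ifelse(mat[, 3L] == "N", "0", mat[, 3L])
      a2 <- ifelse(mat[, 4L] == "N", "0", mat[, 4L])
      geno[cbind(mat[, 2L], mat[, 1L])] <- paste0(a1, a2)
      ped_dataset(placeholder_samples_named(samps),
                  placeholder_snps(sites), unname(geno))
    },
    geo = {
      fields <- split_nonblank(path, "\t")
      assert_rectangular(fields, "GEO input")
      header <- fields[[1L]]
      samps <- header[-1L]
      body <- fields[-1L]
      mat <- body_matrix(body, length(header))
      calls <- t(mat[, -1L, drop = FALSE])
      calls[calls == def$missing_code] <- "00"
      ped_dataset(placeholder_samples_named(samps),
                  placeholder_snps(mat[, 1L]), calls)
    },
    linkage = read_ped(path),
    gslinkage = {
      lines <- read_text_lines(path)
      keep <- nzchar(trimws(lines))
      lines <- lines[keep]
      if (!length(lines)) {
        abort("empty GS-linkage file", class = "pedkit_parse_error")
      }
      snp_ids <- ws_split(lines[[1L]])[[1L]][-(1:6)]
      tmp <- tempfile(fileext = ".ped")
      on.exit(unlink(tmp))
      write_text_lines(lines[-1L], tmp)
      ds <- read_ped(tmp)
      if (length(snp_ids) == n_snps(ds)) ds$snps$snp_id <- snp_ids
      ds
    }
  )
}

placeholder_samples_named <- function(ids) {
  n <- length(ids)
  tibble(family_id = ids, individual_id = ids,
         paternal_id = rep("0", n), maternal_id = rep("0", n),
         sex = rep("0", n), phenotype = rep("0", n))
}

split_nonblank <- function(path, delim = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(delim)) ws_split(lines) else
    strsplit(lines, delim, fixed = TRUE)
}

body_matrix <- function(fields, width) {
  if (!length(fields)) return(matrix(character(), 0L, width))
  matrix(unlist(fields), ncol = width, byrow = TRUE)
}
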