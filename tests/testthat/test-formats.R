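test_that("additive and letter-order codings follow their definitions", {
  expect_equal(code_additive(c("AA", "AC", "CC", "00"), "A", "C"),
               c(0L, 1L, 2L, 3L))
  expect_equal(code_additive("CA", "A", "C"), 1L)
  # letter order ignores which allele is major
  expect_equal(code_letter_order(c("AA", "AC", "CC"), "C", "A"),
               c(0L, 1L, 2L))
  expect_equal(code_letter_order("CA", "C", "A"), 1L)
  # when the major allele sorts first the codings coincide
  for (call in c("AA", "AC", "CC", "00")) {
    expect_equal(code_letter_order(call, "A", "C"),
                 code_additive(call, "A", "C"))
  }
  expect_error(code_additive("GG", "A", "C"), class = "pedkit_internal_error")
})

test_that("additive code plus major-allele count is two", {
  withr::with_seed(41, {
    ds <- sim_ped_dataset(20, 8, missing_rate = 0.1)
    summ <- allele_summary(ds)
    for (j in seq_len(n_snps(ds))) {
      calls <- ds$genotypes[, j]
      g <- code_additive(calls, summ$major[[j]], summ$minor[[j]])
      maj_count <- (substr(calls, 1, 1) == summ$major[[j]]) +
        (substr(calls, 2, 2) == summ$major[[j]])
      keep <- g != 3L
      expect_equal(g[keep] + maj_count[keep], rep(2, sum(keep)))
    }
  })
})

test_that("every importable format round-trips the genotype grid", {
  formats <- format_registry()
  importable <- formats$format[formats$importer]
  withr::with_seed(42, {
    for (rep in 1:6) {
      ds <- sim_ped_dataset(sample(2:15, 1), sample(1:8, 1),
                            missing_rate = runif(1, 0, 0.25))
      nm <- normalize_genotypes(ds)
      for (f in importable) {
        path <- tmp_path(paste0("x.", f))
        export_dataset(ds, f, path)
        back <- suppressMessages(import_dataset(path, f))
        raw_format <- formats$coding[formats$format == f] == "raw-alleles"
        if (raw_format) {
          expect_true(grids_equal(ds$genotypes, back$genotypes),
                      label = paste(f, "raw grid"))
        } else {
          # coded formats lift to the D/d alphabet
          expect_identical(back$genotypes, nm$genotypes,
                           label = paste(f, "coded grid"))
        }
        if (formats$phenotype[formats$format == f] != "none") {
          expect_identical(back$samples$phenotype, ds$samples$phenotype,
                           label = paste(f, "phenotype"))
        }
        expect_equal(n_snps(back), n_snps(ds), label = paste(f, "snp count"))
      }
    }
  })
})

test_that("exports are byte-deterministic", {
  ds <- sim_ped_dataset(6, 4, missing_rate = 0.1, seed = 43)
  for (f in format_registry()$format) {
    p1 <- tmp_path("a.out"); p2 <- tmp_path("b.out")
    export_dataset(ds, f, p1)
    export_dataset(ds, f, p2)
    expect_identical(readLines(p1), readLines(p2), label = f)
  }
})

test_that("MDR export carries a SNP-name header with trailing Class", {
  ds <- sim_ped_dataset(3, 2, seed = 44)
  p <- tmp_path("m.mdr")
  export_dataset(ds, "mdr", p)
  lines <- readLines(p)
  expect_equal(lines[[1]], "rs1\trs2\tClass")
  expect_equal(length(lines), 4L)
  expect_true(all(grepl("\t[01]$", lines[-1])))
})

test_that("BOOST and BEAM layouts match their descriptors", {
  ds <- sim_ped_dataset(4, 3, seed = 45)
  pb <- tmp_path("b.boost")
  export_dataset(ds, "boost", pb)
  lines <- readLines(pb)
  expect_equal(length(lines), 4L)
  expect_true(all(grepl("^[01] ", lines)))  # class label first

  pm <- tmp_path("b.beam")
  export_dataset(ds, "beam", pm)
  beam <- readLines(pm)
  expect_equal(length(beam), 1L + 3L)       # status row + one row per SNP
  expect_match(beam[[1]], "^ID Chr Pos ")
  expect_match(beam[[2]], "^rs1 1 ")
})

test_that("unsupported phenotypes are rejected by case/control formats", {
  ds <- sim_ped_dataset(4, 2, seed = 46)
  ds$samples$phenotype <- c("1.5", "2.3", "0.7", "1.1")  # quantitative
  expect_error(export_dataset(ds, "mdr", tmp_path("q.mdr")),
               class = "pedkit_export_error")
  expect_error(export_logicreg(ds, tmp_path("q.lr"), logited = TRUE),
               class = "pedkit_export_error")
  # non-logited logic regression passes the quantitative phenotype through
  p <- tmp_path("ok.lr")
  export_logicreg(ds, p, model = "additive", logited = FALSE)
  expect_match(readLines(p)[[1]], "^1\\.5 ")
})

test_that("logic-regression recoding enumerates all six combinations", {
  # brute-force table over g in {0,1,2} for the three models
  expected <- list(dominant = c(0L, 1L, 1L), recessive = c(0L, 0L, 1L),
                   additive = c(0L, 1L, 2L))
  geno <- matrix(c("AA", "AC", "CC"), 3, 1)
  ds <- ped_dataset(
    tibble::tibble(family_id = paste0("F", 1:3),
                   individual_id = paste0("I", 1:3), paternal_id = "0",
                   maternal_id = "0", sex = "1",
                   phenotype = c("2", "1", "2")),
    tibble::tibble(chrom = "1", snp_id = "rs1", cm = 0, bp = 1), geno)
  # the AA/AC/CC column has A major, so rows carry g = 0, 1, 2
  for (model in names(expected)) {
    for (logited in c(FALSE, TRUE)) {
      p <- tmp_path("lr.txt")
      export_logicreg(ds, p, model = model, logited = logited)
      fields <- do.call(rbind, strsplit(readLines(p), " "))
      expect_equal(as.integer(fields[, 2]), expected[[model]],
                   label = paste(model, logited))
      expect_equal(fields[, 1],
                   if (logited) c("1", "0", "1") else c("2", "1", "2"))
    }
  }
})

test_that("PrettyBase writes one line per sample-site pair and auto-detects dialects", {
  ds <- sim_ped_dataset(5, 4, missing_rate = 0.2, seed = 47)
  p <- tmp_path("pb.txt")
  export_dataset(ds, "prettybase", p)  # seattlesnps (tab) by default
  expect_equal(length(readLines(p)), 5L * 4L)
  expect_equal(detect_prettybase_version(p), "seattlesnps")

  p2 <- tmp_path("pb2.txt")
  export_dataset(ds, "prettybase", p2, indicators = list(version = "slider"))
  expect_equal(detect_prettybase_version(p2), "slider")
  back <- suppressMessages(import_dataset(p2, "prettybase"))
  expect_true(grids_equal(ds$genotypes, back$genotypes))

  empty <- tmp_path("empty.txt")
  writeLines(character(0), empty)
  expect_error(detect_prettybase_version(empty), class = "pedkit_parse_error")
  odd <- tmp_path("odd.txt")
  writeLines("a b", odd)
  expect_error(detect_prettybase_version(odd), class = "pedkit_parse_error")
})

test_that("GEO no-call tokens import as missing", {
  geo <- tmp_path("g.geo")
  writeLines(c("ID_REF\tS1\tS2", "rs1\tAC\tNC"), geo)
  ds <- import_dataset(geo, "geo")
  expect_equal(ds$genotypes[1, 1], "AC")
  expect_equal(ds$genotypes[2, 1], "00")
})

test_that("invalid numeric codes are rejected on import", {
  bad <- tmp_path("bad.boost")
  writeLines(c("1 0 1", "0 2 7"), bad)
  expect_error(import_dataset(bad, "boost"), "7",
               class = "pedkit_parse_error")
})

test_that("unknown formats and indicators fail before any I/O", {
  ds <- sim_ped_dataset(3, 2, seed = 48)
  expect_error(export_dataset(ds, "hapmap", tmp_path("x")),
               class = "pedkit_config_error")
  out <- tmp_path("x.mdr")
  expect_error(export_dataset(ds, "mdr", out, indicators = list(foo = 1)),
               class = "pedkit_config_error")
  expect_false(file.exists(out))
  expect_error(import_dataset(tmp_path("y"), "logicreg"),
               class = "pedkit_config_error")
})

test_that("CSV and space-delimited text convert both ways", {
  f <- tmp_path("t.txt")
  writeLines(c("a b c", "d e f"), f)
  out <- tmp_path("t.csv")
  csv_space_convert(f, out, "to-csv")
  expect_equal(readLines(out), c("a,b,c", "d,e,f"))
  back <- tmp_path("t2.txt")
  csv_space_convert(out, back, "to-space")
  expect_equal(readLines(back), c("a b c", "d e f"))

  # quoting on the way to CSV
  writeLines("x y,z", f)
  csv_space_convert(f, out, "to-csv")
  expect_equal(readLines(out), "x,\"y,z\"")
  # a space inside a CSV field cannot be space-delimited
  writeLines("\"a b\",c", out)
  expect_error(csv_space_convert(out, back, "to-space"),
               class = "pedkit_export_error")
})

test_that("csv round trip collapses whitespace only", {
  withr::with_seed(49, {
    for (rep in 1:5) {
      width <- sample(2:5, 1)
      rows <- replicate(sample(2:6, 1),
                        paste(sample(letters, width), collapse = "  "))
      f <- tmp_path("r.txt"); mid <- tmp_path("r.csv"); back <- tmp_path("r2.txt")
      writeLines(rows, f)
      csv_space_convert(f, mid, "to-csv")
      csv_space_convert(mid, back, "to-space")
      expect_equal(readLines(back), gsub(" +", " ", trimws(rows)))
    }
  })
})
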