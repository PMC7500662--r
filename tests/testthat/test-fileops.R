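ex_path <- function(f) system.file("extdata/compare", f, package = "pedkit")

test_that("sequential comparison of the worked example finds five rows", {
  rep <- compare_files(ex_path("ex1.dat"), ex_path("ex2.dat"))
  expect_equal(nrow(rep$differing_rows), 5L)
  expect_equal(rep$differing_rows$row, 1:5)
})

test_that("reference-keyed comparison reduces the example to one row", {
  rep <- compare_files(ex_path("ex1.dat"), ex_path("ex2.dat"),
                       mode = "reference", ref_col = 2)
  expect_equal(nrow(rep$differing_rows), 1L)
  expect_equal(rep$differing_rows$key, "SNP2")
  expect_equal(rep$differing_rows$columns[[1]], 4L)
  expect_length(rep$rows_only_in_a, 0)
  expect_length(rep$rows_only_in_b, 0)
})

test_that("comparing a file with itself gives an empty report", {
  rep <- compare_files(ex_path("ex1.dat"), ex_path("ex1.dat"))
  expect_equal(nrow(rep$differing_rows), 0L)
  expect_true(glance(rep)$identical)
})

test_that("whitespace-only differences do not count", {
  a <- tmp_path("a.txt"); b <- tmp_path("b.txt")
  writeLines("x  y\tz ", a)
  writeLines(" x y z", b)
  expect_equal(nrow(compare_files(a, b)$differing_rows), 0L)
})

test_that("comparison difference counts are symmetric", {
  withr::with_seed(61, {
    for (rep in 1:8) {
      a <- tmp_path("a.txt"); b <- tmp_path("b.txt")
      keys <- paste0("k", 1:6)
      mk <- function() paste(keys, sample(0:2, 6, TRUE), sample(0:2, 6, TRUE))
      writeLines(sample(mk()), a)
      writeLines(sample(mk()), b)
      seq_ab <- compare_files(a, b)
      seq_ba <- compare_files(b, a)
      expect_equal(nrow(seq_ab$differing_rows), nrow(seq_ba$differing_rows))
      ref_ab <- compare_files(a, b, mode = "reference", ref_col = 1)
      ref_ba <- compare_files(b, a, mode = "reference", ref_col = 1)
      expect_equal(nrow(ref_ab$differing_rows), nrow(ref_ba$differing_rows))
      # same key set: reordering can only reduce differences
      expect_lte(nrow(ref_ab$differing_rows), nrow(seq_ab$differing_rows))
    }
  })
})

test_that("reference-mode input validation", {
  a <- tmp_path("a.txt"); b <- tmp_path("b.txt")
  writeLines(c("k1 1", "k1 2"), a)
  writeLines(c("k1 1", "k2 2"), b)
  expect_error(compare_files(a, b, mode = "reference", ref_col = 1),
               "k1", class = "pedkit_comparison_error")
  writeLines(c("k1 1", "k2"), a)
  expect_error(compare_files(a, b, mode = "reference", ref_col = 2),
               "row 2", class = "pedkit_parse_error")
  expect_error(compare_files(a, b, mode = "reference"),
               class = "pedkit_config_error")
})

test_that("binary files are compared bytewise", {
  a <- tmp_path("a.bin"); b <- tmp_path("b.bin")
  writeBin(as.raw(c(0, 1, 2, 3)), a)
  writeBin(as.raw(c(0, 9, 2, 3)), b)
  rep <- compare_files(a, b)
  expect_equal(rep$mode, "binary")
  expect_equal(rep$differing_rows$row, 2)
  expect_equal(nrow(compare_files(a, a)$differing_rows), 0L)
})

test_that("transpose maps cells, is an involution and mode-independent", {
  f <- tmp_path("g.txt")
  writeLines(c("a b c", "d e f"), f)
  out <- tmp_path("gt.txt")
  transpose_file(f, out, mode = "speed")
  expect_equal(readLines(out), c("a d", "b e", "c f"))
  back <- tmp_path("gb.txt")
  transpose_file(out, back, mode = "speed")
  expect_equal(readLines(back), readLines(f))

  withr::with_seed(62, {
    for (rep in 1:8) {
      nr <- sample(1:30, 1); nc <- sample(1:30, 1)
      grid <- matrix(sample(c(LETTERS, 0:9), nr * nc, TRUE), nr, nc)
      writeLines(apply(grid, 1, paste, collapse = " "), f)
      o1 <- tmp_path("t1.txt"); o2 <- tmp_path("t2.txt")
      transpose_file(f, o1, mode = "speed")
      transpose_file(f, o2, mode = "memory", block_cols = sample(1:7, 1))
      expect_identical(readLines(o1), readLines(o2))
      expect_identical(readBin(o1, "raw", file.size(o1)),
                       readBin(o2, "raw", file.size(o2)))
    }
  })
})

test_that("ragged input is rejected by transpose with the offending row", {
  f <- tmp_path("r.txt")
  writeLines(c("a b", "c"), f)
  expect_error(transpose_file(f, tmp_path("o.txt"), mode = "speed"),
               "row 2", class = "pedkit_parse_error")
  expect_error(transpose_file(f, tmp_path("o.txt"), mode = "memory"),
               "row 2", class = "pedkit_parse_error")
})

test_that("auto transpose logs its mode selection", {
  f <- tmp_path("a.txt")
  writeLines(c("a b", "c d"), f)
  expect_message(transpose_file(f, tmp_path("o.txt"), mode = "auto"),
                 "speed-first")
  expect_message(transpose_file(f, tmp_path("o2.txt"), mode = "auto",
                                mem_limit = 1),
                 "memory-first")
})

test_that("row and column insertion follow patterns and positions", {
  f <- tmp_path("m.txt")
  writeLines(c("A A C C", "G G T T"), f)
  out <- tmp_path("mi.txt")
  insert_rows_cols(f, out, data.frame(axis = "row", position = 1,
                                      pattern = "SNP$"))
  expect_equal(readLines(out)[[1]], "SNP1 SNP2 SNP3 SNP4")

  insert_rows_cols(f, out, data.frame(axis = "col", position = 1,
                                      pattern = "0"))
  expect_equal(readLines(out), c("0 A A C C", "0 G G T T"))

  # multiple insertions in one pass, applied in declared order
  insert_rows_cols(f, out, data.frame(axis = c("row", "col"),
                                      position = c(1, 1),
                                      pattern = c("h$", "@")))
  expect_equal(readLines(out),
               c("1 h1 h2 h3 h4", "2 A A C C", "3 G G T T"))

  expect_error(insert_rows_cols(f, out,
                                data.frame(axis = "row", position = 9,
                                           pattern = "x")),
               class = "pedkit_config_error")
})

test_that("deletion removes listed indices and inverts insertion", {
  f <- tmp_path("d.txt")
  writeLines(c("r1 a b c", "r2 d e f", "r3 g h i"), f)
  out <- tmp_path("do.txt")
  delete_rows_cols(f, out, rows = 2)
  expect_equal(readLines(out), c("r1 a b c", "r3 g h i"))
  delete_rows_cols(f, out, cols = c(1, 3))
  expect_equal(readLines(out), c("a c", "d f", "g i"))
  delete_rows_cols(f, out)
  expect_equal(readLines(out), readLines(f))
  expect_error(delete_rows_cols(f, out, rows = 7),
               "7", class = "pedkit_config_error")

  ins <- tmp_path("i.txt")
  insert_rows_cols(f, ins, data.frame(axis = "row", position = 2,
                                      pattern = "x"))
  delete_rows_cols(ins, out, rows = 2)
  expect_equal(readLines(out), readLines(f))
})

test_that("splicing merges samples over aligned SNPs", {
  dir <- tmp_path("")
  sp <- sim_splice_pair(dir, n_a = 4, n_b = 6, n_shared = 0, n_snps = 5,
                        seed = 63)
  out <- splice_ped(sp$a$ped, sp$b$ped, file.path(dir, "out.ped"),
                    map_a = sp$a$map, map_b = sp$b$map)
  expect_equal(n_samples(out), 10L)

  # one shared six-column prefix: the A copy wins
  sp2 <- sim_splice_pair(dir, n_a = 4, n_b = 4, n_shared = 1, n_snps = 5,
                         seed = 64)
  out2 <- splice_ped(sp2$a$ped, sp2$b$ped, file.path(dir, "out2.ped"),
                     map_a = sp2$a$map, map_b = sp2$b$map)
  expect_equal(n_samples(out2), 7L)
  expect_equal(n_samples(out2), sp2$expected_spliced_samples)
})

test_that("SNPs absent from one file are set missing in its samples", {
  a <- sim_ped_dataset(3, 3, seed = 65)
  b <- sim_ped_dataset(2, 2, seed = 66)
  b$samples$individual_id <- c("B1", "B2")
  b$snps$snp_id <- c("rs2", "rs9")  # rs2 shared, rs9 new; rs1/rs3 A-only
  b$genotypes <- a$genotypes[1:2, c(2, 1)]  # rs2 column compatible with A's
  out <- splice_datasets(a, b)
  expect_equal(out$snps$snp_id, c("rs1", "rs2", "rs3", "rs9"))
  # A's SNP order leads, B-only appended
  expect_equal(n_samples(out), 5L)
  # B-origin samples are missing at A-only SNPs, and vice versa
  expect_true(all(out$genotypes[4:5, c(1, 3)] == "00"))
  expect_true(all(out$genotypes[1:3, 4] == "00"))
})

test_that("self-splice is the identity", {
  dir <- tmp_path("")
  ds <- sim_ped_dataset(5, 4, missing_rate = 0.1, seed = 67)
  ped <- file.path(dir, "self.ped"); map <- file.path(dir, "self.map")
  write_ped(ds, ped, map)
  out <- splice_ped(ped, ped, file.path(dir, "out.ped"),
                    map_a = map, map_b = map)
  expect_identical(out$genotypes, ds$genotypes)
  expect_identical(out$samples, ds$samples)
})

test_that("conflicting alleles across files abort the splice", {
  a <- sim_ped_dataset(3, 1, seed = 68)
  b <- a
  b$samples$individual_id <- paste0("B", 1:3)
  # force a third allele at the shared SNP
  other <- setdiff(c("A", "C", "G", "T"),
                   unique(unlist(strsplit(a$genotypes[, 1], ""))))[1:2]
  b$genotypes <- matrix(paste0(other[1], other[2]), 3, 1)
  expect_error(splice_datasets(a, b), "rs1",
               class = "pedkit_multiallelic_error")
})

test_that("comparison reports serialize to text and TSV", {
  rep <- compare_files(ex_path("ex1.dat"), ex_path("ex2.dat"))
  out <- tmp_path("report.txt")
  write_comparison_report(rep, out)
  expect_match(paste(readLines(out), collapse = "\n"), "differing rows: 5")
  tsv <- read.delim(paste0(out, ".tsv"))
  expect_equal(nrow(tsv), sum(lengths(rep$differing_rows$columns)))
  expect_equal(nrow(tidy(rep)), nrow(tsv))
})
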