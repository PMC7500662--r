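test_that("PED layout follows the single-space contract", {
  ds <- ped_dataset(
    tibble::tibble(family_id = "F1", individual_id = "I1", paternal_id = "0",
                   maternal_id = "0", sex = "1", phenotype = "1"),
    tibble::tibble(chrom = "1", snp_id = "rs1", cm = 0, bp = 100),
    matrix("AC", 1, 1))
  ped <- tmp_path("one.ped")
  write_ped(ds, ped)
  expect_equal(readLines(ped), "F1 I1 0 0 1 1 A C")

  # degenerate: zero SNPs still emits the six pedigree columns
  ds0 <- ped_dataset(ds$samples,
                     tibble::tibble(chrom = character(), snp_id = character(),
                                    cm = numeric(), bp = numeric()),
                     matrix(character(), 1, 0))
  ped0 <- tmp_path("zero.ped")
  write_ped(ds0, ped0)
  expect_equal(readLines(ped0), "F1 I1 0 0 1 1")
})

test_that("PED read/write is the identity on generated datasets", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      ds <- sim_ped_dataset(sample(1:20, 1), sample(0:10, 1),
                            missing_rate = runif(1, 0, 0.3))
      ped <- tmp_path("rt.ped"); map <- tmp_path("rt.map")
      write_ped(ds, ped, map)
      back <- read_ped(ped, map)
      expect_identical(back$genotypes, ds$genotypes)
      expect_identical(back$samples, ds$samples)
      expect_identical(back$snps$snp_id, ds$snps$snp_id)
    }
  })
})

test_that("malformed PED input is rejected with row context", {
  ped <- tmp_path("bad.ped")
  writeLines(c("F1 I1 0 0 1", "F2 I2 0 0 1"), ped)  # 5 leading fields
  expect_error(read_ped(ped), class = "pedkit_parse_error")

  writeLines(c("F1 I1 0 0 1 1 A C A", "F2 I2 0 0 1 1 A C A"), ped)
  expect_error(read_ped(ped), "odd", class = "pedkit_parse_error")

  writeLines(c("F1 I1 0 0 1 1 A C", "F2 I2 0 0 1 1 A C A A"), ped)
  expect_error(read_ped(ped), "row 2", class = "pedkit_parse_error")

  # MAP/PED SNP count mismatch
  writeLines("F1 I1 0 0 1 1 A C", ped)
  map <- tmp_path("bad.map")
  writeLines(c("1 rs1 0 1", "1 rs2 0 2"), map)
  expect_error(read_ped(ped, map), class = "pedkit_structure_error")
})

test_that("a PED without a MAP gets placeholder marker records", {
  ped <- tmp_path("nomap.ped")
  writeLines("F1 I1 0 0 1 1 A C G G", ped)
  ds <- read_ped(ped)
  expect_equal(ds$snps$snp_id, c("snp_1", "snp_2"))
  expect_equal(ds$snps$chrom, c("0", "0"))
})

test_that("multi-character alleles are reduced with a warning", {
  ped <- tmp_path("multi.ped")
  writeLines("F1 I1 0 0 1 1 ACG T", ped)
  expect_warning(ds <- read_ped(ped), "multi-character")
  expect_equal(ds$genotypes[1, 1], "AT")
})

test_that("BED payload size follows ceil(n/4) x m exactly", {
  for (n in 1:9) {
    for (m in 1:9) {
      ds <- sim_ped_dataset(n, m, seed = n * 100 + m)
      bed <- tmp_path("s.bed")
      write_bed(ds, bed, tmp_path("s.bim"), tmp_path("s.fam"))
      expect_equal(file.size(bed), 3 + ceiling(n / 4) * m)
    }
  }
})

test_that("BED round trip preserves genotypes as unordered pairs", {
  withr::with_seed(32, {
    for (rep in 1:10) {
      ds <- sim_ped_dataset(sample(1:25, 1), sample(1:10, 1),
                            missing_rate = runif(1, 0, 0.3))
      bed <- tmp_path("r.bed"); bim <- tmp_path("r.bim"); fam <- tmp_path("r.fam")
      write_bed(ds, bed, bim, fam)
      back <- read_bed(bed, bim, fam)
      expect_true(grids_equal(ds$genotypes, back$genotypes))
      expect_identical(back$samples, ds$samples)
      expect_identical(back$snps$snp_id, ds$snps$snp_id)
    }
  })
})

test_that("BED files agree with an independent bit-level decoder", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      ds <- sim_ped_dataset(sample(3:20, 1), sample(1:8, 1),
                            missing_rate = 0.1)
      bed <- tmp_path("o.bed"); bim <- tmp_path("o.bim"); fam <- tmp_path("o.fam")
      write_bed(ds, bed, bim, fam)
      expect_true(grids_equal(ds$genotypes, oracle_read_bed(bed, bim, fam)))
    }
  })
})

test_that("corrupt BED input is diagnosed", {
  ds <- sim_ped_dataset(5, 3, seed = 34)
  bed <- tmp_path("c.bed"); bim <- tmp_path("c.bim"); fam <- tmp_path("c.fam")
  write_bed(ds, bed, bim, fam)

  raw <- readBin(bed, "raw", n = file.size(bed))
  writeBin(raw[-length(raw)], truncated <- tmp_path("t.bed"))
  expect_error(read_bed(truncated, bim, fam), "payload",
               class = "pedkit_parse_error")

  raw2 <- raw; raw2[1] <- as.raw(0xFF)
  writeBin(raw2, wrong <- tmp_path("w.bed"))
  expect_error(read_bed(wrong, bim, fam), "not a BED",
               class = "pedkit_parse_error")

  raw3 <- raw; raw3[3] <- as.raw(0x00)
  writeBin(raw3, indiv <- tmp_path("i.bed"))
  expect_error(read_bed(indiv, bim, fam), "individual-major",
               class = "pedkit_parse_error")
})

test_that("TPED layout and round trip preserve SNP order", {
  ds <- ped_dataset(
    tibble::tibble(family_id = c("F1", "F2"), individual_id = c("I1", "I2"),
                   paternal_id = "0", maternal_id = "0", sex = "1",
                   phenotype = "1"),
    tibble::tibble(chrom = "1", snp_id = "rs1", cm = 0, bp = 100),
    matrix(c("AC", "AA"), 2, 1))
  tped <- tmp_path("t.tped"); tfam <- tmp_path("t.tfam")
  write_tped(ds, tped, tfam)
  expect_equal(readLines(tped), "1 rs1 0 100 A C A A")
  expect_equal(length(readLines(tfam)), 2L)

  withr::with_seed(35, {
    for (rep in 1:8) {
      ds <- sim_ped_dataset(sample(1:15, 1), sample(1:10, 1),
                            missing_rate = runif(1, 0, 0.2))
      write_tped(ds, tped, tfam)
      back <- read_tped(tped, tfam)
      expect_identical(back$genotypes, ds$genotypes)
      expect_identical(back$snps$snp_id, ds$snps$snp_id)
    }
  })
})

test_that(".tsnp sidecar replaces marker ids, with count checking", {
  ds <- sim_ped_dataset(4, 3, seed = 36)
  tped <- tmp_path("s.tped"); tfam <- tmp_path("s.tfam")
  write_tped(ds, tped, tfam)
  tsnp <- tmp_path("s.tsnp")
  writeLines(c("rs901 1", "rs902 2", "rs903 3"), tsnp)
  back <- read_tped(tped, tfam, tsnp)
  expect_equal(back$snps$snp_id, c("rs901", "rs902", "rs903"))
  # configurable RS column
  writeLines(c("1 rs911", "2 rs912", "3 rs913"), tsnp)
  back2 <- read_tped(tped, tfam, tsnp, tsnp_col = 2)
  expect_equal(back2$snps$snp_id, c("rs911", "rs912", "rs913"))
  # row-count mismatch names both counts
  writeLines(c("rs901", "rs902"), tsnp)
  expect_error(read_tped(tped, tfam, tsnp), "2.*3|3.*2",
               class = "pedkit_structure_error")
})

test_that("conversion chains preserve sample and SNP order", {
  ds <- sim_ped_dataset(7, 6, missing_rate = 0.1, seed = 37)
  tped <- tmp_path("c.tped"); tfam <- tmp_path("c.tfam")
  bed <- tmp_path("c.bed"); bim <- tmp_path("c.bim"); fam <- tmp_path("c.fam")
  write_tped(ds, tped, tfam)
  mid <- read_tped(tped, tfam)
  write_bed(mid, bed, bim, fam)
  final <- read_bed(bed, bim, fam)
  expect_identical(final$snps$snp_id, ds$snps$snp_id)
  expect_identical(final$samples$individual_id, ds$samples$individual_id)
  expect_true(grids_equal(final$genotypes, ds$genotypes))
})
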