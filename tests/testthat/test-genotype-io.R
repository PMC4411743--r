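test_that("bed decoding follows the PLINK 1.9 two-bit convention", {
  # one individual, one variant, homozygous A2 -> code 11 -> dosage 0
  td <- withr::local_tempdir()
  writeLines("1\trs1\t0\t100\tA\tG", file.path(td, "x.bim"))
  writeLines("f1\ti1\t0\t0\t0\t-9", file.path(td, "x.fam"))
  con <- file(file.path(td, "x.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x03)), con)
  close(con)
  g <- read_plink(file.path(td, "x"))
  expect_equal(unname(g$dosages[1, 1]), 0)

  # all four codes in one byte: 00 01 10 11 packed low-bits-first
  writeLines("1\trs1\t0\t100\tA\tG", file.path(td, "y.bim"))
  writeLines(paste0("f", 1:4, "\ti", 1:4, "\t0\t0\t0\t-9"),
             file.path(td, "y.fam"))
  con <- file(file.path(td, "y.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xe4)), con)  # 11 10 01 00
  close(con)
  g <- read_plink(file.path(td, "y"))
  expect_equal(unname(g$dosages[, 1]), c(2, NA, 1, 0))
})

test_that("bed write/read roundtrip is bit-identical, missing preserved", {
  set.seed(42)
  g <- simulate_genotypes(50, 100)
  dos <- g$dosages
  dos[sample(length(dos), 80)] <- NA
  g <- genotype_matrix(dos, g$variants[c("id", "chr", "pos", "a1", "a2")],
                       g$samples)
  td <- withr::local_tempdir()
  write_plink(g, file.path(td, "a"))
  g2 <- read_plink(file.path(td, "a"))
  expect_identical(unname(g2$dosages), unname(g$dosages))
  write_plink(g2, file.path(td, "b"))
  expect_identical(readBin(file.path(td, "a.bed"), "raw", n = 1e6),
                   readBin(file.path(td, "b.bed"), "raw", n = 1e6))
})

test_that("malformed bed files are rejected with specific errors", {
  td <- withr::local_tempdir()
  writeLines("1\trs1\t0\t100\tA\tG", file.path(td, "x.bim"))
  writeLines("f1\ti1\t0\t0\t0\t-9", file.path(td, "x.fam"))
  con <- file(file.path(td, "x.bed"), "wb")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x03)), con); close(con)
  expect_error(read_plink(file.path(td, "x")), "magic")

  con <- file(file.path(td, "x.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x03)), con); close(con)
  expect_error(read_plink(file.path(td, "x")), "sample-major")

  con <- file(file.path(td, "x.bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con); close(con)
  expect_error(read_plink(file.path(td, "x")), "truncated")

  expect_error(read_plink(file.path(td, "nope")), "missing")
})

test_that("sumstats reader validates, preserves order, handles OR", {
  p <- tmp_lines(c("SNP A1 A2 BETA", "rs3 A G 0.2", "rs1 C T -0.1",
                   "rs2 G A 0.05"))
  ss <- read_table_input(p, "sumstats")
  expect_equal(ss$id, c("rs3", "rs1", "rs2"))
  expect_equal(ss$beta, c(0.2, -0.1, 0.05))

  por <- tmp_lines(c("SNP A1 A2 OR", "rs1 A G 1.5"))
  expect_equal(read_table_input(por, "sumstats")$beta, log(1.5))

  pdup <- tmp_lines(c("SNP A1 A2 BETA", "rs1 A G 0.2", "rs1 C T 0.1"))
  expect_error(read_table_input(pdup, "sumstats"), "rs1")
  expect_error(read_table_input(tmp_lines(character()), "sumstats"), "empty")
})

test_that("phenotype/environment readers flag missing and check kinds", {
  p <- tmp_lines(c("f1 i1 1", "f2 i2 NA", "f3 i3 0"))
  ph <- read_table_input(p, "phenotype")
  expect_true(is.na(ph$value[2]))
  expect_equal(attr(ph, "kind"), "binary")

  pe <- tmp_lines(c("f1 i1 0", "f2 i2 2"))
  expect_error(read_table_input(pe, "environment", kind = "binary"),
               "binary")
  pp <- tmp_lines(c("rs1 setA", "rs2 setA", "rs3 setB"))
  part <- read_table_input(pp, "partition")
  expect_equal(part$partition, c("setA", "setA", "setB"))
})

test_that("GCTA binary GRM roundtrips exactly at float32", {
  td <- withr::local_tempdir()
  # 2x2 identity: file order over pairs (1,1),(2,1),(2,2) -> 1, 0, 1
  id2 <- new_grm(diag(2), data.frame(fid = c("a", "b"), iid = c("a", "b")),
                 n_snps = 10, kind = "genetic")
  write_grm(id2, file.path(td, "i2"))
  con <- file(file.path(td, "i2.grm.bin"), "rb")
  vals <- readBin(con, "numeric", 3, size = 4, endian = "little")
  close(con)
  expect_equal(vals, c(1, 0, 1))
  expect_equal(read_grm(file.path(td, "i2"))$values, id2$values)

  set.seed(7)
  g <- simulate_genotypes(100, 300)
  A <- compute_grm(g)
  write_grm(A, file.path(td, "g"))
  A2 <- read_grm(file.path(td, "g"))
  expect_lt(max(abs(A2$values - A$values)),
            2^-23 * max(abs(A$values)) * 4)
  expect_equal(A2$n_snps, matrix(A$n_snps, 100, 100), ignore_attr = TRUE)

  # triangle length inconsistent with id count
  writeLines(c("a a", "b b", "c c"), file.path(td, "bad.grm.id"))
  con <- file(file.path(td, "bad.grm.bin"), "wb")
  writeBin(numeric(10), con, size = 4); close(con)
  expect_error(read_grm(file.path(td, "bad")), "inconsistent")
})
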