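test_that("marker map enforces its invariants", {
  expect_error(marker_map(c(1, 1), c("a", "a"), c(1, 2)), "duplicate marker")
  expect_error(marker_map(c(1, 1), c("a", "b"), c(5, 5)),
               "strictly increasing")
  expect_error(marker_map(1, "a", 0), ">= 1")
  mp <- marker_map(c(2, 1, 1), c("a", "b", "c"), c(10, 30, 20))
  # grouped by chromosome, sorted within
  expect_equal(mp$marker_id, c("a", "c", "b"))
})

test_that("genotype dataset validates shape, codes and labels", {
  mp <- marker_map(c(1, 1), c("a", "b"), c(10, 20))
  smp <- data.frame(sample_id = c("s1", "s2"), population = "P")
  expect_error(genotype_dataset(matrix(0L, 3, 2), mp, smp), "rows")
  expect_error(genotype_dataset(matrix(3L, 2, 2), mp, smp), "codes")
  smp2 <- smp; smp2$population <- c("P", "")
  expect_error(genotype_dataset(matrix(0L, 2, 2), mp, smp2), "non-empty")
  ds <- genotype_dataset(matrix(c(0L, 1L, 2L, NA), 2, 2), mp, smp)
  expect_equal(dim(ds), c(2L, 2L))
})

test_that("PED text genotypes recode to A2 dosage with PLINK missing convention", {
  dir <- withr::local_tempdir()
  writeLines(c("P1 s1 0 0 0 -9 A A A G G G",
               "P1 s2 0 0 0 -9 G G 0 0 A A"),
             file.path(dir, "t.ped"))
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200", "1\tm3\t0\t300"),
             file.path(dir, "t.map"))
  ds <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"),
                        a2 = c("G", "G", "G"))
  expect_equal(unname(ds$genotypes[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(ds$genotypes[2, ]), c(2L, NA, 0L))
  expect_equal(ds$samples$population, c("P1", "P1"))
  # first-observed convention when a2 is not given: A2 = A at m1
  ds2 <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_equal(unname(ds2$genotypes[, 1]), c(2L, 0L))
  # realignment restores the reference orientation
  expect_equal(unname(align_alleles(ds2, c("G", "G", "G"))$genotypes),
               unname(ds$genotypes))
})

test_that("text reader rejects malformed PED input", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tm1\t0\t100", "1\tm2\t0\t200"), file.path(dir, "t.map"))
  writeLines(c("P s1 0 0 0 -9 A A G G",
               "P s2 0 0 0 -9 A A"), file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"),
                               file.path(dir, "t.map")), "ragged PED line 2")
  writeLines(c("P s1 0 0 0 -9 A A G G",
               "P s2 0 0 0 -9 C C G G",
               "P s3 0 0 0 -9 T T G G"), file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"),
                               file.path(dir, "t.map")), "more than 2 alleles")
  writeLines(c("P s1 0 0 0 -9 A A G G",
               "P s1 0 0 0 -9 A A G G"), file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"),
                               file.path(dir, "t.map")), "duplicate sample")
  writeLines("P s1 0 0 0 -9 A 0 G G", file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"),
                               file.path(dir, "t.map")), "half-missing")
})

test_that("binary reader decodes the PLINK 1.9 bit layout exactly", {
  dir <- withr::local_tempdir()
  # 3 samples x 2 markers; marker 1 dosages (0,1,2) -> codes 00,10,11
  # packed low bits first: 0 + 2*4 + 3*16 = 56; marker 2 (NA,2,0) -> 13
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 56, 13)), file.path(dir, "t.bed"))
  writeLines(c("1\tm1\t0\t100\tA\tG", "1\tm2\t0\t200\tC\tT"),
             file.path(dir, "t.bim"))
  writeLines(c("P s1 0 0 0 -9", "P s2 0 0 0 -9", "P s3 0 0 0 -9"),
             file.path(dir, "t.fam"))
  ds <- read_plink_binary(file.path(dir, "t.bed"), file.path(dir, "t.bim"),
                          file.path(dir, "t.fam"))
  expect_equal(unname(ds$genotypes),
               matrix(c(0L, 1L, 2L, NA, 2L, 0L), 3, 2))
  expect_equal(ds$map$a2, c("G", "T"))
  # bad magic and truncation
  writeBin(as.raw(c(0x6c, 0x00, 0x01, 1)), file.path(dir, "bad.bed"))
  expect_error(read_plink_binary(file.path(dir, "bad.bed"),
                                 file.path(dir, "t.bim"),
                                 file.path(dir, "t.fam")), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 56)), file.path(dir, "tr.bed"))
  expect_error(read_plink_binary(file.path(dir, "tr.bed"),
                                 file.path(dir, "t.bim"),
                                 file.path(dir, "t.fam")), "truncated")
})

test_that("text and binary formats round-trip and agree on random datasets", {
  dir <- withr::local_tempdir()
  for (seed in 1:25) {
    ds <- random_dataset(seed, n = sample(2:20, 1), m = sample(10:80, 1))
    write_plink_text(ds, file.path(dir, "t"))
    write_plink_binary(ds, file.path(dir, "b"))
    # binary round-trip is exact (BIM fixes the orientation)
    back_b <- read_plink_binary(file.path(dir, "b.bed"),
                                file.path(dir, "b.bim"),
                                file.path(dir, "b.fam"))
    expect_identical(back_b$genotypes, ds$genotypes)
    expect_identical(back_b$samples, ds$samples)
    # text round-trip is exact after orientation alignment
    back_t <- align_alleles(read_plink_text(file.path(dir, "t.ped"),
                                            file.path(dir, "t.map")),
                            ds$map$a2)
    expect_identical(back_t$genotypes, ds$genotypes)
    expect_identical(back_t$map$pos_bp, ds$map$pos_bp)
    # cross-format equivalence
    expect_identical(back_t$genotypes, back_b$genotypes)
  }
})

test_that("allele frequencies count A2 copies over called genotypes", {
  mk <- function(col) {
    n <- length(col)
    genotype_dataset(matrix(as.integer(col), n, 1),
                     marker_map("1", "m1", 100),
                     data.frame(sample_id = paste0("s", 1:n),
                                population = "P"))
  }
  expect_equal(allele_frequencies(mk(c(0, 0, 0, 0)))$p, 0)
  expect_equal(allele_frequencies(mk(c(0, 1, 2)))$p, 0.5)
  expect_equal(allele_frequencies(mk(c(2, NA, 1)))$p, 0.75)
  # bounded and invariant under sample permutation
  for (seed in 1:20) {
    ds <- random_dataset(seed)
    p1 <- allele_frequencies(ds)$p
    expect_true(all(p1 >= 0 & p1 <= 1, na.rm = TRUE))
    perm <- sample(nrow(ds$genotypes))
    ds2 <- subset_dataset(ds, samples = perm)
    expect_equal(allele_frequencies(ds2)$p, p1)
  }
})

test_that("HWE exact test matches brute-force enumeration", {
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), oracle_hwe(1, 0, 1),
               tolerance = 1e-12)
  for (n in 1:6) {
    for (n1 in 0:n) for (nh in 0:(n - n1)) {
      n2 <- n - n1 - nh
      expect_equal(hwe_exact_test(n1, nh, n2), oracle_hwe(n1, nh, n2),
                   tolerance = 1e-12,
                   label = sprintf("hwe(%d,%d,%d)", n1, nh, n2))
    }
  }
})

test_that("QC applies filters in fixed order with a reconciled report", {
  set.seed(99)
  ds <- random_dataset(1, n = 10, m = 40, missing_rate = 0)
  # marker 1: 8/10 called (below 0.90); marker 2: MAF 0.05-ish monomorphic
  ds$genotypes[1:2, 1] <- NA
  ds$genotypes[, 2] <- 0L
  ds$genotypes[, 3] <- c(1L, rep(0L, 9))    # MAF 0.05, kept at threshold
  out <- apply_qc(ds, qc_config("strict", hwe_p_min = 0))
  st <- out$report$steps
  expect_equal(st$removed[st$filter == "marker_call_rate"], 1L)
  expect_false("snp1" %in% out$dataset$map$marker_id)
  expect_false("snp2" %in% out$dataset$map$marker_id)  # monomorphic: MAF 0
  expect_true("snp3" %in% out$dataset$map$marker_id)   # MAF 0.05 >= 0.05
  # lenient track keeps rare and monomorphic markers
  out_l <- apply_qc(ds, qc_config("lenient"))
  expect_true(all(c("snp2", "snp3") %in% out_l$dataset$map$marker_id))
  # retained + removed reconcile
  m_removed <- sum(st$removed[st$unit == "marker"])
  expect_equal(m_removed + length(out$report$markers_retained),
               ncol(ds$genotypes))
})

test_that("QC drops non-autosomal markers and is idempotent", {
  ds <- random_dataset(3, n = 12, m = 30, missing_rate = 0.02)
  ds$map$chrom[1:5] <- "X"
  cfg <- qc_config("strict")
  out1 <- apply_qc(ds, cfg)
  expect_equal(out1$report$steps$removed[1], 5L)
  out2 <- apply_qc(out1$dataset, cfg)
  expect_identical(out2$dataset$genotypes, out1$dataset$genotypes)
  expect_true(all(out2$report$steps$removed == 0))
  # all-markers-removed is an explicit error
  ds$map$chrom[] <- "X"
  expect_error(apply_qc(ds, cfg), "no autosomal markers|all markers")
})
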