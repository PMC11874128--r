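toy_track <- function(fractions, pos = NULL, population = "P",
                      chrom = "1", kind = "ROH") {
  m <- length(fractions)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = m)
  data.frame(population = population, kind = kind, chrom = chrom,
             pos_bp = pos, marker_id = paste0("m", seq_len(m)),
             n_in_run = round(fractions * 10), n_genotyped = 10,
             fraction = fractions)
}

manual_runset <- function(df, kind = "ROH") {
  df$kind <- rep_len(kind, nrow(df))
  df$length_bp <- df$end_bp - df$start_bp + 1
  df$n_snp <- rep_len(10L, nrow(df))
  df$length_class <- classify_run_length(df$length_bp, kind)
  structure(list(runs = df, kind = kind,
                 params = if (kind == "ROH") roh_params() else rohet_params()),
            class = "run_set")
}

test_that("incidence fractions count covering runs over genotyped samples", {
  ds <- random_dataset(8, n = 10, m = 40, n_pop = 1, missing_rate = 0,
                       n_chrom = 1)
  pos <- ds$map$pos_bp
  # empty run set: all zero
  rs0 <- manual_runset(data.frame(sample_id = character(0),
                                  population = character(0),
                                  chrom = character(0),
                                  start_bp = numeric(0), end_bp = numeric(0)))
  tr0 <- incidence_track(rs0, ds)
  expect_true(all(tr0$fraction == 0))
  # 6 of 10 samples covered at marker 20
  rs <- manual_runset(data.frame(sample_id = sprintf("s%02d", 1:6),
                                 population = "POP1", chrom = "1",
                                 start_bp = pos[15], end_bp = pos[25]))
  tr <- incidence_track(rs, ds)
  expect_equal(tr$fraction[20], 0.6)
  expect_equal(tr$n_in_run[20], 6)
  expect_equal(tr$fraction[5], 0)
  # missing genotypes shrink the denominator
  ds$genotypes[1:2, 20] <- NA
  tr2 <- incidence_track(rs, ds)
  expect_equal(tr2$n_genotyped[20], 8)
  expect_equal(tr2$fraction[20], 6 / 8)
})

test_that("threshold resolution covers absolute, quantile and combined modes", {
  tr <- toy_track(c(rep(0, 999), 1))
  expect_equal(resolve_threshold(tr, threshold_spec("absolute", 0.5)), 0.5)
  expect_gt(resolve_threshold(tr, threshold_spec("top_quantile", 0.001)),
            0.99)
  const <- toy_track(rep(0.4, 50))
  expect_equal(resolve_threshold(const, threshold_spec("top_quantile", 0.1)),
               0.4)
  # constant track at its own quantile: ties included, all SNPs hotspot
  isl <- call_islands(const, threshold_spec("top_quantile", 0.1))
  expect_equal(sum(isl$n_snp), 50)
  expect_equal(resolve_threshold(const,
                                 threshold_spec("combined", 0.1,
                                                absolute_value = 0.5)), 0.5)
})

test_that("island calling merges consecutive hotspot SNPs by gap", {
  fr <- rep(0.1, 60)
  fr[11:15] <- 0.6
  tr <- toy_track(fr)
  isl <- call_islands(tr, threshold_spec("absolute", 0.5))
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start_bp, tr$pos_bp[11])
  expect_equal(isl$end_bp, tr$pos_bp[15])
  expect_equal(isl$n_snp, 5L)
  expect_equal(isl$peak_fraction, 0.6)
  # no SNP above threshold: empty result
  expect_equal(nrow(call_islands(toy_track(rep(0.2, 30)),
                                 threshold_spec("absolute", 0.5))), 0L)
  # two clusters 2 Mb apart with a 500 kb merge gap stay separate
  fr2 <- rep(0, 60); fr2[5:8] <- 0.8; fr2[29:32] <- 0.8
  isl2 <- call_islands(toy_track(fr2), threshold_spec("absolute", 0.5))
  expect_equal(nrow(isl2), 2L)
  # island membership is exactly the thresholded set
  for (i in seq_len(nrow(isl2))) {
    member <- tr$pos_bp >= isl2$start_bp[i] & tr$pos_bp <= isl2$end_bp[i]
    expect_true(all(fr2[member] >= isl2$resolved_threshold[i]))
  }
})

test_that("quantile mode keeps at most ceil(q m) hotspot SNPs plus ties", {
  for (seed in 1:10) {
    set.seed(seed)
    fr <- round(runif(200), 2)
    tr <- toy_track(fr)
    q <- 0.05
    thr <- resolve_threshold(tr, threshold_spec("top_quantile", q))
    n_hot <- sum(fr >= thr)
    n_ties <- sum(fr == thr)
    expect_lte(n_hot, ceiling(q * 200) + n_ties)
  }
})

test_that("island overlaps intersect intervals across populations", {
  isl <- data.frame(population = c("A", "B"), kind = "ROH", chrom = "1",
                    start_bp = c(10e6, 15e6), end_bp = c(20e6, 25e6),
                    n_snp = 10L, peak_fraction = 0.7, mean_fraction = 0.6,
                    resolved_threshold = 0.5)
  ov <- overlap_islands(isl)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$start_bp, 15e6)
  expect_equal(ov$end_bp, 20e6)
  expect_equal(ov$populations, "A,B")
  # identical islands: the shared region is the island
  isl2 <- isl; isl2$start_bp <- 10e6; isl2$end_bp <- 20e6
  ov2 <- overlap_islands(isl2)
  expect_equal(c(ov2$start_bp, ov2$end_bp), c(10e6, 20e6))
  # disjoint islands: empty
  isl3 <- isl; isl3$start_bp <- c(1e6, 30e6); isl3$end_bp <- c(2e6, 40e6)
  expect_equal(nrow(overlap_islands(isl3)), 0L)
  # three-way overlap reports the full population set
  isl4 <- rbind(isl, data.frame(population = "C", kind = "ROH", chrom = "1",
                                start_bp = 18e6, end_bp = 22e6, n_snp = 5L,
                                peak_fraction = 0.6, mean_fraction = 0.55,
                                resolved_threshold = 0.5))
  ov4 <- overlap_islands(isl4, min_populations = 3)
  expect_equal(nrow(ov4), 1L)
  expect_equal(c(ov4$start_bp, ov4$end_bp), c(18e6, 20e6))
})

test_that("annotation converts BED coordinates and measures overlaps", {
  dir <- withr::local_tempdir()
  isl <- data.frame(population = "P", kind = "ROH", chrom = "1",
                    start_bp = 100, end_bp = 200, n_snp = 3L,
                    peak_fraction = 0.6, mean_fraction = 0.6,
                    resolved_threshold = 0.5)
  # BED is 0-based half-open: 99-150 -> 1-based [100, 150], overlap 51 bp
  writeLines(c("1\t99\t150\tgeneA", "1\t200\t260\tgeneB"),
             file.path(dir, "ann.bed"))
  ann <- annotate_islands(isl, file.path(dir, "ann.bed"))
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$feature, "geneA")
  expect_equal(ann$overlap_bp, 51)
  # geneB starts at 1-based 201 = end+1: abutting, no overlap
  expect_false("geneB" %in% ann$feature)
  # GFF3 input (1-based inclusive)
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t150\t300\t.\t+\t.\tID=geneC"),
             file.path(dir, "ann.gff3"))
  ann2 <- annotate_islands(isl, file.path(dir, "ann.gff3"))
  expect_equal(ann2$overlap_bp, 51)   # [150, 200]
  # empty annotation: empty result, no error
  writeLines(character(0), file.path(dir, "empty.bed"))
  expect_equal(nrow(annotate_islands(isl, file.path(dir, "empty.bed"))), 0L)
})

test_that("planted islands are recalled with few false calls across seeds", {
  hits <- 0; false_calls <- 0; n_rep <- 25
  for (seed in seq_len(n_rep)) {
    ped <- build_pedigree(population_design("P", 20, "founder_pairs"))
    cfg <- sim_config(n_chromosomes = 1, chromosome_length_bp = 3e7,
                      markers_per_chromosome = 600, missing_rate = 0.005,
                      rng_seed = 6000 + seed)
    sim <- gene_drop(ped, cfg)
    out <- plant_islands(sim$dataset, sim$truth,
                         island_spec("1", 1e7, 1.6e7, "roh", 0.6, "P"),
                         seed = 7000 + seed)
    roh <- detect_roh(out$dataset)
    tr <- incidence_track(roh, out$dataset)
    isl <- call_islands(tr, threshold_spec("absolute", 0.5))
    overlap <- isl$end_bp >= 1e7 & isl$start_bp <= 1.6e7
    if (any(overlap)) hits <- hits + 1
    false_calls <- false_calls + sum(!overlap)
  }
  expect_gte(hits, n_rep - 1)
  expect_lte(false_calls, ceiling(0.05 * n_rep))
})
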