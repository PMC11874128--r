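# construct a single-sample chromosome with given genotype vector / spacing
.homog <- function(n, spacing) rep(0L, n)

test_that("ROH caller handles the canonical constructed cases", {
  # 80 homozygous SNPs spaced 25 kb over ~2 Mb: one run covering SNP 1..80
  pos <- seq(25e3, by = 25e3, length.out = 80)
  ds <- vector_dataset(rep(2L, 80), pos)
  rs <- detect_roh(ds)
  expect_equal(nrow(rs$runs), 1L)
  expect_equal(rs$runs$start_bp, pos[1])
  expect_equal(rs$runs$end_bp, pos[80])
  expect_equal(rs$runs$n_snp, 80L)
  # fully heterozygous sample: zero runs
  expect_equal(nrow(detect_roh(vector_dataset(rep(1L, 80), pos))$runs), 0L)
  # 60 homozygous SNPs spanning only 0.8 Mb: fails the 1 Mb length criterion
  pos08 <- seq(13e3, by = 13e3, length.out = 60)
  expect_equal(nrow(detect_roh(vector_dataset(rep(0L, 60), pos08))$runs), 0L)
  # chromosome shorter than the window yields no calls with a warning
  expect_warning(out <- detect_roh(vector_dataset(rep(0L, 10),
                                                  seq_len(10) * 5e4)),
                 "< 50 markers")
  expect_equal(nrow(out$runs), 0L)
})

test_that("ROHet caller applies the consecutive-SNP criteria", {
  pos <- seq(40e3, by = 40e3, length.out = 15)   # 15 SNPs spanning 600 kb
  rs <- detect_rohet(vector_dataset(rep(1L, 15), pos))
  expect_equal(nrow(rs$runs), 1L)
  expect_equal(rs$runs$n_snp, 15L)
  # 14 consecutive heterozygous SNPs: below the minimum
  rs14 <- detect_rohet(vector_dataset(rep(1L, 14), pos[1:14]))
  expect_equal(nrow(rs14$runs), 0L)
  # 20 het SNPs interrupted by 4 homozygotes: equals oracle enumeration
  g <- rep(1L, 24); g[c(5, 9, 13, 17)] <- 0L
  pos24 <- seq(30e3, by = 30e3, length.out = 24)
  imp <- run_matrix(detect_rohet(vector_dataset(g, pos24)), pos24)
  ora <- oracle_rohet(g, pos24, rohet_params())
  expect_identical(unname(imp), unname(ora))
})

test_that("run callers equal brute-force interval enumeration on random instances", {
  for (seed in 1:60) {
    inst <- random_run_instance(seed + 9000)
    ds <- vector_dataset(inst$g, inst$pos)
    expect_identical(
      unname(suppressWarnings(run_matrix(detect_roh(ds, inst$roh_p),
                                         inst$pos))),
      unname(oracle_roh(inst$g, inst$pos, inst$roh_p)),
      label = paste("ROH vs oracle, seed", seed + 9000))
    expect_identical(
      unname(suppressWarnings(run_matrix(detect_rohet(ds, inst$rohet_p),
                                         inst$pos))),
      unname(oracle_rohet(inst$g, inst$pos, inst$rohet_p)),
      label = paste("ROHet vs oracle, seed", seed + 9000))
  }
})

test_that("run detection is monotone in its thresholds and never overlaps", {
  for (seed in 1:25) {
    inst <- random_run_instance(seed + 500)
    ds <- vector_dataset(inst$g, inst$pos)
    p <- inst$roh_p
    base <- suppressWarnings(detect_roh(ds, p))
    # raising the minimum length never increases the number of runs
    p_long <- p; p_long$min_length_bp <- p$min_length_bp * 2
    expect_lte(nrow(suppressWarnings(detect_roh(ds, p_long))$runs),
               nrow(base$runs))
    # lowering the window het budget never increases total ROH bp
    if (p$window_het_max > 0) {
      p_tight <- p
      p_tight$window_het_max <- p$window_het_max - 1
      p_tight$run_het_max <- p_tight$window_het_max
      expect_lte(sum(suppressWarnings(detect_roh(ds, p_tight))$runs$length_bp),
                 sum(base$runs$length_bp))
    }
    # no overlap within sample/chromosome, runs sorted
    for (rs in list(base, suppressWarnings(detect_rohet(ds, inst$rohet_p)))) {
      r <- rs$runs
      if (nrow(r) > 1) {
        expect_true(all(r$start_bp[-1] > r$end_bp[-nrow(r)]))
      }
    }
  }
})

test_that("a planted homozygous segment is recovered within one marker interval", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- 600
    pos <- seq(5e4, by = 5e4, length.out = m)   # 30 Mb chromosome
    # heterozygosity-rich background, 5 Mb homozygous segment in the middle
    g <- sample(c(0L, 1L, 2L), m, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    seg <- which(pos >= 12e6 & pos <= 17e6)
    g[seg] <- sample(c(0L, 2L), length(seg), replace = TRUE)
    # double heterozygous flanks: extension past the segment would exceed
    # the run-level heterozygote budget
    g[min(seg) - (1:2)] <- 1L; g[max(seg) + (1:2)] <- 1L
    rs <- detect_roh(vector_dataset(g, pos))
    hit <- rs$runs[rs$runs$end_bp >= 12e6 & rs$runs$start_bp <= 17e6, ]
    expect_equal(nrow(hit), 1L)
    expect_lte(abs(hit$start_bp - 12e6), 5e4 + 1)
    expect_lte(abs(hit$end_bp - 17e6), 5e4 + 1)
  }
})

test_that("length classes use half-open bins with an unbounded top class", {
  expect_equal(as.character(classify_run_length(3.5e6, "ROH")), "2-4 Mb")
  expect_equal(as.character(classify_run_length(2.0e6, "ROH")), "2-4 Mb")
  expect_equal(as.character(classify_run_length(1.2e6, "ROHet")), "1-1.5 Mb")
  expect_equal(as.character(classify_run_length(c(1e6, 8e6, 9e9), "ROH")),
               c("1-2 Mb", ">8 Mb", ">8 Mb"))
  expect_equal(as.character(classify_run_length(5e5, "ROHet")), "0.5-1 Mb")
  expect_equal(as.character(classify_run_length(2e6, "ROHet")), ">2 Mb")
})

test_that("run summaries report counts, means and coverage percentages", {
  pos <- seq(25e3, by = 25e3, length.out = 200)
  runs <- data.frame(sample_id = "s1", population = "P", kind = "ROH",
                     chrom = "1", start_bp = c(1e6, 5e6),
                     end_bp = c(2.5e6, 8e6), n_snp = c(60L, 120L),
                     length_bp = c(1.5e6, 3e6))
  runs$length_class <- classify_run_length(runs$length_bp, "ROH")
  rs <- structure(list(runs = runs, kind = "ROH", params = roh_params()),
                  class = "run_set")
  sm <- summarize_runs(rs)
  cs <- sm$class_summary
  expect_equal(cs$n_runs[match(c("1-2 Mb", "2-4 Mb", "4-8 Mb", ">8 Mb"),
                               cs$length_class)], c(1L, 1L, 0L, 0L))
  expect_equal(cs$coverage_pct[cs$length_class == "1-2 Mb"], 100 * 1.5 / 4.5)
  expect_equal(cs$coverage_pct[cs$length_class == "2-4 Mb"], 100 * 3 / 4.5)
  # empty run set: zero counts, flagged undefined coverage
  rs0 <- structure(list(runs = runs[0, ], kind = "ROH",
                        params = roh_params()), class = "run_set")
  sm0 <- summarize_runs(rs0, samples = data.frame(sample_id = "s1",
                                                  population = "P"))
  expect_true(all(sm0$class_summary$n_runs == 0))
  expect_true(all(sm0$class_summary$coverage_pct == 0))
  expect_true(all(sm0$class_summary$undefined_coverage))
  # mean runs per sample: 2, 4, 6 runs -> 4
  runs3 <- do.call(rbind, lapply(1:3, function(i) {
    k <- 2 * i
    data.frame(sample_id = paste0("s", i), population = "P", kind = "ROH",
               chrom = "1", start_bp = 1e6 * seq_len(k),
               end_bp = 1e6 * seq_len(k) + 1.4e6, n_snp = 60L,
               length_bp = 1.4e6)
  }))
  runs3$length_class <- classify_run_length(runs3$length_bp, "ROH")
  rs3 <- structure(list(runs = runs3, kind = "ROH", params = roh_params()),
                   class = "run_set")
  ps <- summarize_runs(rs3)$per_sample
  expect_equal(mean(ps$n_runs), 4)
})
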