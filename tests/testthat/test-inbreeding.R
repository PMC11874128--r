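make_runset <- function(lengths_bp, sample_id = "s1", kind = "ROH",
                        population = "P") {
  n <- length(lengths_bp)
  runs <- data.frame(sample_id = rep_len(sample_id, n),
                     population = rep_len(population, n),
                     kind = rep_len(kind, n),
                     chrom = rep_len("1", n),
                     start_bp = if (n) cumsum(c(1, utils::head(lengths_bp, -1) + 1e6)) else numeric(0),
                     n_snp = rep_len(60L, n), length_bp = lengths_bp)
  runs$end_bp <- runs$start_bp + runs$length_bp - 1
  runs$length_class <- classify_run_length(lengths_bp, kind)
  structure(list(runs = runs, kind = kind,
                 params = if (kind == "ROH") roh_params() else rohet_params()),
            class = "run_set")
}

test_that("F_ROH is summed run length over the map extent, split by class", {
  smp <- data.frame(sample_id = "s1", population = "P")
  ltot <- 2468749207     # a chip-scale autosomal extent as fixture
  expect_equal(f_roh(make_runset(numeric(0)), ltot, samples = smp)$f_roh_total, 0)
  one <- f_roh(make_runset(ltot), ltot, samples = smp)
  expect_equal(one$f_roh_total, 1)
  fr <- f_roh(make_runset(c(1.5e6, 2e6, 119937460)), ltot, samples = smp)
  expect_equal(fr$f_roh_total, 123437460 / ltot, tolerance = 1e-9)
  expect_equal(fr$f_roh_total, 0.05, tolerance = 1e-4)
  # class decomposition sums exactly to the total
  cls <- fr[, grep("^f_roh_", names(fr))]
  expect_equal(sum(cls[, -match("f_roh_total", names(cls))]), fr$f_roh_total,
               tolerance = 1e-12)
  expect_equal(fr$`f_roh_1_2_Mb`, 1.5e6 / ltot)
  expect_equal(fr$`f_roh_2_4_Mb`, 2e6 / ltot)
})

test_that("genome extent sums per-chromosome marker spans", {
  map <- marker_map(c(1, 1, 1, 2, 2, "X", "X"),
                    paste0("m", 1:7), c(100, 500, 900, 10, 4000, 1, 50))
  expect_equal(genome_extent(map), (900 - 100 + 1) + (4000 - 10 + 1))
})

test_that("VanRaden G matches closed forms and HWE expectation", {
  mkds <- function(G, pops = "P") {
    m <- ncol(G)
    genotype_dataset(G, marker_map(rep("1", m), paste0("m", seq_len(m)),
                                   seq_len(m) * 1e4),
                     data.frame(sample_id = paste0("s", seq_len(nrow(G))),
                                population = pops))
  }
  # every sample heterozygous at every marker, p = 0.5: Z = 0, F_G = -1
  ds_het <- mkds(matrix(1L, 4, 6))
  gr <- grm_vanraden(ds_het)
  expect_true(all(abs(gr$G) < 1e-12))
  expect_equal(unname(gr$f_g), rep(-1, 4))
  # single marker, p = 0.5, dosages (2, 0): G_ii = 1 / 0.5 = 2, F_G = 1
  gr2 <- grm_vanraden(mkds(matrix(c(2L, 0L), 2, 1)))
  expect_equal(unname(diag(gr2$G)), c(2, 2))
  expect_equal(unname(gr2$f_g), c(1, 1))
  # uncentered literal coding for comparison
  gr_raw <- grm_vanraden(mkds(matrix(c(2L, 0L), 2, 1)), center = FALSE)
  expect_equal(unname(gr_raw$G[1, 1]), 4 / 0.5)
  # all-monomorphic input is an error
  expect_error(grm_vanraden(mkds(matrix(2L, 3, 4))), "monomorphic")
  # HWE-simulated unrelated samples: mean F_G ~ 0, mean diagonal ~ 1
  set.seed(77)
  n <- 400; m <- 4000
  p <- runif(m, 0.1, 0.9)
  G <- sapply(p, function(pj) rbinom(n, 2, pj))
  gr3 <- grm_vanraden(mkds(G))
  expect_lt(abs(mean(gr3$f_g)), 0.02)
  expect_lt(abs(mean(diag(gr3$G)) - 1), 0.02)
  expect_true(isSymmetric(gr3$G, tol = 1e-10))
})

test_that("F_exH matches a hand-evaluated spreadsheet computation", {
  # 3 samples x 4 markers, no missing
  G <- matrix(c(0L, 1L, 2L,
                2L, 2L, 2L,
                1L, 1L, 0L,
                0L, 0L, 1L), 3, 4)
  ds <- genotype_dataset(G, marker_map(rep("1", 4), paste0("m", 1:4),
                                       c(1e4, 2e4, 3e4, 4e4)),
                         data.frame(sample_id = c("a", "b", "c"),
                                    population = "P"))
  fe <- f_exh(ds)
  # manual: p = (3/6, 6/6, 2/6, 1/6); expected homozygosity per marker with
  # the n/(n-1) correction; the monomorphic marker contributes obs = exp = 1
  p <- c(0.5, 1, 1 / 3, 1 / 6)
  eh <- 1 - 2 * p * (1 - p) * (3 / 2)
  # sample "a": genotypes 0, 2, 1, 0 -> obs_homo = 3 over 4 calls
  exp_a <- sum(eh)
  expect_equal(fe$obs_homo[1], 3)
  expect_equal(fe$total_observation[1], 4)
  expect_equal(fe$f_exh[1], (3 - exp_a) / (4 - exp_a), tolerance = 1e-12)
  # dropping the monomorphic marker leaves F unchanged (obs = exp there)
  exp_a3 <- sum(eh[c(1, 3, 4)])
  expect_equal(fe$f_exh[1], (2 - exp_a3) / (3 - exp_a3), tolerance = 1e-12)
  # a fully homozygous sample scores 1
  G2 <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 2L, 1L, 0L), 3, 3)
  ds2 <- genotype_dataset(G2, marker_map(rep("1", 3), paste0("m", 1:3),
                                         c(1e4, 2e4, 3e4)),
                          data.frame(sample_id = c("a", "b", "c"),
                                     population = "P"))
  fe2 <- f_exh(ds2)
  expect_equal(fe2$f_exh[3], 1)   # sample c: genotypes 2, 2, 0
})

test_that("heterozygosity coefficient has both definitions, agreeing in rank", {
  smp <- data.frame(sample_id = "s1", population = "P")
  expect_equal(het_coefficient(make_runset(numeric(0), kind = "ROHet"),
                               1e9, samples = smp)$het_coefficient, 0)
  expect_equal(het_coefficient(make_runset(c(5e7, 5e7), kind = "ROHet"),
                               1e9, samples = smp)$het_coefficient, 0.1)
  # 20 samples with heterozygous blocks of increasing size
  m <- 400
  pos <- seq(5e4, by = 5e4, length.out = m)
  G <- matrix(0L, 20, m)
  set.seed(3)
  for (i in 1:20) {
    G[i, ] <- sample(c(0L, 2L), m, replace = TRUE)
    G[i, seq_len(15 + 8 * i)] <- 1L
  }
  ds <- genotype_dataset(G, marker_map(rep("1", m), paste0("m", seq_len(m)),
                                       pos),
                         data.frame(sample_id = sprintf("s%02d", 1:20),
                                    population = "P"))
  rs <- detect_rohet(ds)
  h1 <- het_coefficient(rs, genome_extent(ds), samples = ds$samples)
  h2 <- het_coefficient(rs, dataset = ds, samples = ds$samples,
                        definition = "snp_fraction")
  expect_gt(cor(h1$het_coefficient, h2$het_coefficient, method = "spearman"),
            0.9)
})

test_that("inbreeding correlations reproduce the direct formula", {
  set.seed(5)
  tab <- data.frame(sample_id = paste0("s", 1:10),
                    x = rnorm(10))
  tab$y <- 2 * tab$x + 1
  tab$z <- rnorm(10)
  cc <- inbreeding_correlations(tab, columns = c("x", "y", "z"))
  expect_equal(unname(diag(cc$r)), c(1, 1, 1))
  expect_equal(cc$r["x", "y"], 1)
  # direct textbook formula for r
  x <- tab$x; z <- tab$z
  r_direct <- sum((x - mean(x)) * (z - mean(z))) /
    sqrt(sum((x - mean(x))^2) * sum((z - mean(z))^2))
  expect_equal(cc$r["x", "z"], r_direct, tolerance = 1e-12)
  expect_true(isSymmetric(cc$r))
  expect_error(inbreeding_correlations(tab[1:2, ], columns = c("x", "z")),
               "at least 3")
})
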