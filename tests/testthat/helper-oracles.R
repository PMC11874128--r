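# Independent brute-force oracles used across the suite. These deliberately
# recompute everything by literal enumeration (no code shared with the
# package internals beyond the public parameter objects).

# All passing ROH intervals by full interval enumeration, then greedy
# left-to-right disjoint selection (leftmost start, ties to rightmost end).
oracle_roh <- function(g, pos, p) {
  m <- length(g)
  if (m < p$window_snp) return(cbind(integer(0), integer(0)))
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  W <- p$window_snp
  nw <- m - W + 1L
  hit <- vapply(seq_len(nw), function(i)
    sum(het[i:(i + W - 1)]) <= p$window_het_max &&
    sum(mis[i:(i + W - 1)]) <= p$window_missing_max, logical(1))
  eligible <- vapply(seq_len(m), function(j) {
    wins <- max(1, j - W + 1):min(j, nw)
    mean(hit[wins]) >= p$window_hit_fraction
  }, logical(1))

  ch <- c(0, cumsum(het)); ce <- c(0, cumsum(eligible))
  big_gap <- c(FALSE, diff(pos) > p$max_gap_bp)
  cg <- c(0, cumsum(big_gap))
  a <- rep(seq_len(m), times = m)
  b <- rep(seq_len(m), each = m)
  ok <- a <= b &
    hom[a] & hom[b] &
    (ce[b + 1] - ce[a]) == (b - a + 1) &
    (cg[b + 1] - cg[a + 1]) == 0 &      # no oversized gap within (a, b]
    (ch[b + 1] - ch[a]) <= p$run_het_max &
    (b - a + 1) >= p$min_snp &
    (pos[b] - pos[a] + 1) >= p$min_length_bp &
    (pos[b] - pos[a] + 1) / (b - a + 1) <= p$max_density_bp_per_snp
  greedy_select(cbind(a[ok], b[ok]))
}

# All passing ROHet intervals by enumeration, same greedy selection.
oracle_rohet <- function(g, pos, p) {
  m <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  co <- c(0, cumsum(hom)); cm <- c(0, cumsum(mis))
  a <- rep(seq_len(m), times = m)
  b <- rep(seq_len(m), each = m)
  ok <- a <= b &
    het[a] & het[b] &
    (co[b + 1] - co[a]) <= p$max_homozygous &
    (cm[b + 1] - cm[a]) <= p$max_missing &
    (b - a + 1) >= p$min_snp &
    (pos[b] - pos[a] + 1) >= p$min_length_bp
  greedy_select(cbind(a[ok], b[ok]))
}

# naive greedy: repeatedly take the interval with the smallest start (ties:
# largest end) among those starting after the last selected end
greedy_select <- function(ivs) {
  sel <- list()
  last_end <- -Inf
  repeat {
    avail <- ivs[ivs[, 1] > last_end, , drop = FALSE]
    if (!nrow(avail)) break
    s <- min(avail[, 1])
    cand <- avail[avail[, 1] == s, , drop = FALSE]
    e <- max(cand[, 2])
    sel[[length(sel) + 1L]] <- c(s, e)
    last_end <- e
  }
  if (!length(sel)) cbind(integer(0), integer(0)) else do.call(rbind, sel)
}

# exact HWE p-value by direct enumeration of heterozygote counts with
# log-factorial probabilities
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na_ <- 2 * n_hom1 + n_het
  nb_ <- 2 * n - na_
  if (na_ == 0 || nb_ == 0) return(1.0)
  hs <- seq(min(na_, nb_) %% 2, min(na_, nb_), by = 2)
  pr <- vapply(hs, function(h) {
    naa <- (na_ - h) / 2
    nbb <- (nb_ - h) / 2
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
        h * log(2) +
        lfactorial(na_) + lfactorial(nb_) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# random single-sample instance for the run-caller oracle tests: genotype
# state mixes chosen to exercise homozygous stretches, heterozygous
# stretches, missingness and oversized gaps
random_run_instance <- function(seed) {
  set.seed(seed)
  m <- sample(60:200, 1)
  spacing <- runif(m, 1e3, 3e4)
  spike <- runif(m) < 0.04
  spacing[spike] <- runif(sum(spike), 6e4, 4e5)
  pos <- cumsum(ceiling(spacing))
  h <- sample(c(0.02, 0.1, 0.3, 0.7, 0.95), 1)
  r <- runif(m)
  g <- ifelse(r < h, 1L, ifelse(r < h + (1 - h) / 2, 0L, 2L))
  g[runif(m) < 0.03] <- NA_integer_
  roh_p <- roh_params(
    window_snp = sample(c(5, 10, 20), 1),
    window_het_max = sample(0:2, 1),
    window_missing_max = sample(0:1, 1),
    window_hit_fraction = 0.05,
    min_snp = sample(c(5, 10, 15), 1),
    min_length_bp = sample(c(1e5, 3e5), 1),
    max_gap_bp = sample(c(5e4, 1.2e5), 1),
    max_density_bp_per_snp = sample(c(3e4, 1e5), 1))
  rohet_p <- rohet_params(
    min_snp = sample(c(5, 10, 15), 1),
    min_length_bp = sample(c(5e4, 2e5), 1),
    max_missing = sample(0:2, 1),
    max_homozygous = sample(0:3, 1))
  list(g = g, pos = pos, roh_p = roh_p, rohet_p = rohet_p)
}

# wrap a single-sample, single-chromosome genotype vector as a dataset
vector_dataset <- function(g, pos, chrom = "1", population = "P1") {
  map <- marker_map(rep(chrom, length(g)),
                    sprintf("m%d", seq_along(g)), pos)
  genotype_dataset(matrix(as.integer(g), 1), map,
                   data.frame(sample_id = "s1", population = population))
}

# random multi-sample dataset for format and QC tests
random_dataset <- function(seed, n = 10, m = 50, n_pop = 2,
                           missing_rate = 0.05, n_chrom = 2) {
  set.seed(seed)
  chrom <- sort(rep_len(seq_len(n_chrom), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i)
    sort(sample.int(1e6, length(i)))), use.names = FALSE)
  map <- marker_map(chrom, sprintf("snp%d", seq_len(m)), pos,
                    a1 = rep("A", m), a2 = rep("G", m))
  p <- runif(m, 0.05, 0.95)
  G <- sapply(p, function(pj) rbinom(n, 2, pj))
  G[matrix(runif(n * m) < missing_rate, n)] <- NA_integer_
  genotype_dataset(G, map,
                   data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                              population = rep_len(sprintf("POP%d",
                                                           seq_len(n_pop)), n)))
}

run_matrix <- function(runset, pos) {
  # intervals as marker indices for comparison with oracles
  if (!nrow(runset$runs)) return(cbind(integer(0), integer(0)))
  cbind(match(runset$runs$start_bp, pos), match(runset$runs$end_bp, pos))
}
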