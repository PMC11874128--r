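#' Parameters for sliding-window ROH detection
#'
#' Defaults mirror the PLINK `--homozyg` flag family as commonly used on
#' caprine 50-70K arrays: 50-SNP scanning windows allowing at most 1
#' heterozygous and 1 missing call, a 5% window hit-rate for SNP
#' eligibility, runs of at least 50 SNPs and 1 Mb, at most 500 kb between
#' adjacent run SNPs, and an average density of at least 1 SNP per 100 kb.
#'
#' `run_het_max` bounds the heterozygous calls tolerated in a final run
#' (strict reading, default equal to `window_het_max`); set it to `Inf` for
#' the permissive reading where only the window filter limits
#' heterozygosity.
#'
#' @param window_snp scanning-window size in SNPs.
#' @param window_het_max max heterozygous calls per window.
#' @param window_missing_max max missing calls per window.
#' @param window_hit_fraction minimum fraction of overlapping windows that
#'   must be hits for a SNP to be run-eligible.
#' @param min_snp minimum SNPs in a reported run.
#' @param min_length_bp minimum run length in bp.
#' @param max_gap_bp maximum gap between adjacent SNPs inside a run.
#' @param max_density_bp_per_snp maximum average bp per SNP in a run.
#' @param run_het_max run-level heterozygote budget.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snp = 50, window_het_max = 1,
                       window_missing_max = 1, window_hit_fraction = 0.05,
                       min_snp = 50, min_length_bp = 1e6,
                       max_gap_bp = 5e5, max_density_bp_per_snp = 1e5,
                       run_het_max = window_het_max) {
  stopifnot(window_snp >= 1, window_het_max >= 0, window_missing_max >= 0,
            window_hit_fraction > 0, window_hit_fraction <= 1,
            min_snp >= 1, min_length_bp >= 1, max_gap_bp >= 1,
            max_density_bp_per_snp >= 1, run_het_max >= 0)
  structure(list(window_snp = window_snp, window_het_max = window_het_max,
                 window_missing_max = window_missing_max,
                 window_hit_fraction = window_hit_fraction,
                 min_snp = min_snp, min_length_bp = min_length_bp,
                 max_gap_bp = max_gap_bp,
                 max_density_bp_per_snp = max_density_bp_per_snp,
                 run_het_max = run_het_max),
            class = "roh_params")
}

#' Parameters for consecutive-marker ROHet detection
#'
#' Defaults follow the consecutive-SNP heterozygosity-run criteria used on
#' medium-density livestock arrays: at least 15 consecutive SNPs and 500 kb,
#' absorbing at most 2 missing and 3 homozygous calls per run.
#'
#' @param min_snp minimum SNPs in a reported run.
#' @param min_length_bp minimum run length in bp.
#' @param max_missing maximum missing calls absorbed by a run.
#' @param max_homozygous maximum homozygous calls absorbed by a run.
#' @return a `rohet_params` list.
#' @export
rohet_params <- function(min_snp = 15, min_length_bp = 5e5,
                         max_missing = 2, max_homozygous = 3) {
  stopifnot(min_snp >= 1, min_length_bp >= 1, max_missing >= 0,
            max_homozygous >= 0)
  structure(list(min_snp = min_snp, min_length_bp = min_length_bp,
                 max_missing = max_missing, max_homozygous = max_homozygous),
            class = "rohet_params")
}

# ---- internal: one sample x one chromosome ---------------------------------

# Passing ROH interval [a, b] (marker indices): every SNP window-eligible,
# endpoints homozygous, no internal gap > max_gap_bp, total hets <=
# run_het_max, n_snp >= min_snp, length >= min_length_bp, average density
# <= max_density_bp_per_snp. Reported runs are the greedy left-to-right
# disjoint selection over maximal passing intervals (leftmost start first,
# ties broken to the rightmost end), which is also what the brute-force
# enumeration oracle yields.
.roh_eligible <- function(g, p) {
  m <- length(g)
  W <- p$window_snp
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  Ch <- c(0L, cumsum(het)); Cm <- c(0L, cumsum(mis))
  nw <- m - W + 1L
  wh <- Ch[(W + 1):(m + 1)] - Ch[1:nw]
  wm <- Cm[(W + 1):(m + 1)] - Cm[1:nw]
  hit <- (wh <= p$window_het_max) & (wm <= p$window_missing_max)
  Chit <- c(0L, cumsum(hit))
  j <- seq_len(m)
  lo <- pmax(1L, j - W + 1L)
  hi <- pmin(j, nw)
  (Chit[hi + 1L] - Chit[lo]) / (hi - lo + 1L) >= p$window_hit_fraction
}

.roh_chr <- function(g, pos, p) {
  m <- length(g)
  if (m < p$window_snp) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  eligible <- .roh_eligible(g, p)
  if (!any(eligible)) return(NULL)
  hom_idx <- which(hom)
  if (!length(hom_idx)) return(NULL)

  passes_mins <- function(a, b) {
    (b - a + 1L) >= p$min_snp && (pos[b] - pos[a] + 1) >= p$min_length_bp
  }
  density_ok <- function(a, b) {
    (pos[b] - pos[a] + 1) / (b - a + 1L) <= p$max_density_bp_per_snp
  }
  out <- list()

  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (s_i in which(r$values)) {
    s <- starts[s_i]; e <- ends[s_i]
    # split the eligible stretch at physical gaps
    cut_after <- which(diff(pos[s:e]) > p$max_gap_bp) + s - 1L
    piece_starts <- c(s, cut_after + 1L)
    piece_ends <- c(cut_after, e)
    for (k in seq_along(piece_starts)) {
      a0 <- piece_starts[k]; b0 <- piece_ends[k]
      if (b0 - a0 + 1L < p$min_snp) next
      hp <- which(het[a0:b0]) + a0 - 1L
      H <- p$run_het_max
      if (is.infinite(H) || length(hp) <= H) {
        wins <- matrix(c(a0, b0), 1)
      } else {
        # maximal windows holding exactly H heterozygotes; every passing
        # interval of the piece lies inside one of them
        B <- c(a0 - 1L, hp, b0 + 1L)
        t <- seq_len(length(hp) - H + 1L)
        wins <- cbind(B[t] + 1L, B[t + H + 1L] - 1L)
      }
      # greedy left-to-right over passing intervals within the piece:
      # at each resume point, collect for every window its maximal
      # passing interval starting after the resume point (plus, when the
      # window-wide interval fails only the density bound, all dense
      # hom-endpoint sub-intervals), then select leftmost start / longest
      resume <- a0 - 1L
      repeat {
        cand <- list()
        for (w in seq_len(nrow(wins))) {
          wl <- max(wins[w, 1], resume + 1L); wr <- wins[w, 2]
          if (wl > wr) next
          ai <- findInterval(wl - 0.5, hom_idx) + 1L   # first hom >= wl
          bi <- findInterval(wr + 0.5, hom_idx)        # last hom <= wr
          if (ai > bi) next
          a <- hom_idx[ai]; b <- hom_idx[bi]
          if (!passes_mins(a, b)) next
          if (density_ok(a, b)) {
            cand[[length(cand) + 1L]] <- c(a, b)
          } else {
            hs <- hom_idx[ai:bi]
            kk <- length(hs)
            ii <- rep(seq_len(kk), times = kk)
            jj <- rep(seq_len(kk), each = kk)
            sel <- ii < jj
            aa <- hs[ii[sel]]; bb <- hs[jj[sel]]
            ok <- (bb - aa + 1L) >= p$min_snp &
              (pos[bb] - pos[aa] + 1) >= p$min_length_bp &
              (pos[bb] - pos[aa] + 1) / (bb - aa + 1L) <=
                p$max_density_bp_per_snp
            if (any(ok)) {
              cand[[length(cand) + 1L]] <-
                cbind(aa[ok], bb[ok])
            }
          }
        }
        if (!length(cand)) break
        ivs <- do.call(rbind, cand)
        s_min <- min(ivs[, 1])
        b_max <- max(ivs[ivs[, 1] == s_min, 2])
        out[[length(out) + 1L]] <- c(s_min, b_max)
        resume <- b_max
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Passing ROHet interval: heterozygous endpoints, <= max_missing missing and
# <= max_homozygous homozygous calls inside, n_snp >= min_snp, length >=
# min_length_bp. Reported runs are again the greedy left-to-right disjoint
# selection (leftmost start, longest extent), implemented as a two-pointer
# scan over heterozygous marker indices.
.rohet_chr <- function(g, pos, p) {
  het <- !is.na(g) & g == 1L
  hp <- which(het)
  if (!length(hp)) return(NULL)
  mis <- is.na(g)
  hom <- !het & !mis
  Cm <- c(0L, cumsum(mis)); Co <- c(0L, cumsum(hom))
  out <- list()
  k <- 1L
  nh <- length(hp)
  # largest het end q >= a with budgets satisfied on [a, q]
  max_end <- function(a) {
    lo <- match(a, hp); hi <- nh
    # binary search on het index: budgets are monotone in the end position
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      q <- hp[mid]
      if (Cm[q + 1L] - Cm[a] <= p$max_missing &&
          Co[q + 1L] - Co[a] <= p$max_homozygous) lo <- mid else hi <- mid - 1L
    }
    hp[lo]
  }
  while (k <= nh) {
    a <- hp[k]
    b <- max_end(a)
    if ((b - a + 1L) >= p$min_snp && (pos[b] - pos[a] + 1) >= p$min_length_bp) {
      out[[length(out) + 1L]] <- c(a, b)
      k <- findInterval(b, hp) + 1L      # first het strictly after b
    } else {
      k <- k + 1L
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# ---- public callers ---------------------------------------------------------

.build_runset <- function(dataset, kind, params, per_chr_fun, min_markers) {
  G <- dataset$genotypes
  map <- dataset$map
  chroms <- unique(map$chrom)
  short <- character(0)
  rows <- list()
  for (chr in chroms) {
    mi <- which(map$chrom == chr)
    if (length(mi) < min_markers) {
      short <- c(short, chr)
      next
    }
    pos <- map$pos_bp[mi]
    for (s in seq_len(nrow(G))) {
      ivs <- per_chr_fun(G[s, mi], pos, params)
      if (is.null(ivs) || !nrow(ivs)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = dataset$samples$sample_id[s],
        population = dataset$samples$population[s],
        kind = kind, chrom = chr,
        start_bp = pos[ivs[, 1]], end_bp = pos[ivs[, 2]],
        n_snp = ivs[, 2] - ivs[, 1] + 1L,
        length_bp = pos[ivs[, 2]] - pos[ivs[, 1]] + 1,
        stringsAsFactors = FALSE)
    }
  }
  if (length(short)) {
    warning("no ", kind, " calls on chromosome(s) with < ", min_markers,
            " markers: ", paste(short, collapse = ", "))
  }
  runs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), population = character(0),
               kind = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0),
               n_snp = integer(0), length_bp = numeric(0))
  runs$length_class <- classify_run_length(runs$length_bp, kind,
                                           min_length_bp = params$min_length_bp)
  rownames(runs) <- NULL
  structure(list(runs = runs, kind = kind, params = params),
            class = "run_set")
}

#' Detect runs of homozygosity (sliding-window method)
#'
#' Per sample and chromosome: (1) a window of `window_snp` SNPs slides one
#' SNP at a time and is a "hit" when it holds at most `window_het_max`
#' heterozygous and `window_missing_max` missing calls; (2) a SNP is
#' run-eligible when at least `window_hit_fraction` of the windows covering
#' it are hits; (3) within maximal eligible stretches, candidate intervals
#' are trimmed to homozygous terminal SNPs and (4) confined to pieces whose
#' internal marker gaps are at most `max_gap_bp`; (5) an interval passes
#' when it has at least `min_snp` SNPs, spans at least `min_length_bp`, has
#' average density at most `max_density_bp_per_snp` bp per SNP and contains
#' at most `run_het_max` heterozygous calls. The reported run set is the
#' greedy left-to-right disjoint selection over maximal passing intervals.
#'
#' @param dataset a [genotype_dataset()] (lenient-QC marker set).
#' @param params a [roh_params()].
#' @return a `run_set`: `$runs` data.frame (sample_id, population, kind,
#'   chrom, start_bp, end_bp, n_snp, length_bp, length_class) plus the
#'   parameters used.
#' @export
detect_roh <- function(dataset, params = roh_params()) {
  stopifnot(inherits(dataset, "genotype_dataset"), inherits(params, "roh_params"))
  .build_runset(dataset, "ROH", params, .roh_chr, params$window_snp)
}

#' Detect runs of heterozygosity (consecutive-marker method)
#'
#' Per sample and chromosome, the scanner starts a candidate at each
#' heterozygous SNP (left to right) and extends it over consecutive markers
#' while at most `max_missing` missing and `max_homozygous` homozygous
#' calls are absorbed; the candidate ends at the last heterozygous SNP
#' within budget. Candidates with at least `min_snp` SNPs spanning at least
#' `min_length_bp` are reported; the scan resumes after a reported run, so
#' runs never overlap.
#'
#' @param dataset a [genotype_dataset()] (lenient-QC marker set).
#' @param params a [rohet_params()].
#' @return a `run_set` of kind `"ROHet"`.
#' @export
detect_rohet <- function(dataset, params = rohet_params()) {
  stopifnot(inherits(dataset, "genotype_dataset"), inherits(params, "rohet_params"))
  .build_runset(dataset, "ROHet", params, .rohet_chr, 2L)
}

#' @export
print.run_set <- function(x, ...) {
  cat("run_set:", nrow(x$runs), x$kind, "runs in",
      length(unique(x$runs$sample_id)), "samples\n")
  if (nrow(x$runs)) print(table(x$runs$population, x$runs$length_class))
  invisible(x)
}

ROH_CLASS_BOUNDS_MB <- c(1, 2, 4, 8)
ROHET_CLASS_BOUNDS_MB <- c(0.5, 1, 1.5, 2)

#' Length classes for runs
#'
#' Bins run lengths into the four standard length classes; ROH: 1-2, 2-4,
#' 4-8 and >8 Mb; ROHet: 0.5-1.0, 1.0-1.5, 1.5-2.0 and >2.0 Mb. Bins are
#' half-open `[lo, hi)`, so a boundary length falls in the upper class.
#' Lengths below the lowest bound (possible only under non-default
#' detection parameters) get a `<lo Mb` class.
#'
#' @param length_bp numeric vector of run lengths in bp.
#' @param kind `"ROH"` or `"ROHet"`.
#' @param min_length_bp unused except to keep caller signatures uniform.
#' @return factor of class labels, ordered by length.
#' @export
classify_run_length <- function(length_bp, kind = c("ROH", "ROHet"),
                                min_length_bp = NULL) {
  kind <- match.arg(kind)
  bounds <- if (kind == "ROH") ROH_CLASS_BOUNDS_MB else ROHET_CLASS_BOUNDS_MB
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.1f", x))
  labels <- c(paste0("<", fmt(bounds[1]), " Mb"),
              paste0(fmt(bounds[-length(bounds)]), "-", fmt(bounds[-1]), " Mb"),
              paste0(">", fmt(bounds[length(bounds)]), " Mb"))
  idx <- findInterval(length_bp / 1e6, bounds)  # [lo, hi) by default
  factor(labels[idx + 1L], levels = labels, ordered = TRUE)
}

#' Summarise a run set per population and length class
#'
#' Produces the descriptive layer of a run analysis: per population and
#' length class, total run count, mean and SD of per-sample counts, and the
#' coverage percentage (summed run length in the class over the summed run
#' length in the population); plus mean runs per sample and, when a dataset
#' is supplied, the per-chromosome coverage ratio (run bp over chromosome
#' map extent).
#'
#' @param runset a `run_set`.
#' @param samples optional data.frame (`sample_id`, `population`) giving the
#'   full sample list, so samples with zero runs enter the means; defaults
#'   to the samples present in the run set.
#' @param dataset optional [genotype_dataset()] for chromosome extents.
#' @return list with `class_summary`, `per_sample` and (if `dataset` given)
#'   `chromosome_summary` data.frames; empty run sets yield zero counts with
#'   `coverage_pct = 0` and `undefined_coverage = TRUE`.
#' @export
summarize_runs <- function(runset, samples = NULL, dataset = NULL) {
  stopifnot(inherits(runset, "run_set"))
  runs <- runset$runs
  if (is.null(samples)) {
    samples <- unique(runs[, c("sample_id", "population")])
  } else {
    samples <- data.frame(sample_id = as.character(samples$sample_id),
                          population = as.character(samples$population))
  }
  pops <- sort(unique(c(samples$population, runs$population)))
  classes <- levels(runs$length_class)
  grid <- expand.grid(population = pops, length_class = classes,
                      stringsAsFactors = FALSE)
  n_runs <- integer(nrow(grid)); cov <- numeric(nrow(grid))
  mean_ps <- numeric(nrow(grid)); sd_ps <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sel <- runs$population == grid$population[i] &
      as.character(runs$length_class) == grid$length_class[i]
    n_runs[i] <- sum(sel)
    cov[i] <- sum(runs$length_bp[sel])
    ids <- samples$sample_id[samples$population == grid$population[i]]
    per <- vapply(ids, function(s) sum(sel & runs$sample_id == s), numeric(1))
    mean_ps[i] <- if (length(per)) mean(per) else 0
    sd_ps[i] <- if (length(per) > 1) stats::sd(per) else NA_real_
  }
  tot <- tapply(cov, grid$population, sum)[grid$population]
  grid$n_runs <- n_runs
  grid$mean_per_sample <- mean_ps
  grid$sd_per_sample <- sd_ps
  grid$coverage_pct <- ifelse(tot > 0, 100 * cov / tot, 0)
  grid$undefined_coverage <- tot == 0
  grid <- grid[!grepl("^<", grid$length_class) | grid$n_runs > 0, ]

  per_sample <- do.call(rbind, lapply(pops, function(pp) {
    ids <- samples$sample_id[samples$population == pp]
    data.frame(population = pp, sample_id = ids,
               n_runs = vapply(ids, function(s)
                 sum(runs$sample_id == s & runs$population == pp), numeric(1)),
               sum_length_bp = vapply(ids, function(s)
                 sum(runs$length_bp[runs$sample_id == s]), numeric(1)))
  }))
  out <- list(class_summary = grid, per_sample = per_sample)

  if (!is.null(dataset)) {
    map <- dataset$map
    ext <- tapply(map$pos_bp, map$chrom, function(p) max(p) - min(p) + 1)
    chr_grid <- expand.grid(population = pops, chrom = names(ext),
                            stringsAsFactors = FALSE)
    chr_grid$run_bp <- mapply(function(pp, cc)
      sum(runs$length_bp[runs$population == pp & runs$chrom == cc]),
      chr_grid$population, chr_grid$chrom)
    npop <- table(samples$population)[chr_grid$population]
    chr_grid$chrom_extent_bp <- as.numeric(ext[chr_grid$chrom])
    chr_grid$coverage_ratio <- chr_grid$run_bp /
      (chr_grid$chrom_extent_bp * pmax(1, as.numeric(npop)))
    out$chromosome_summary <- chr_grid
  }
  out
}

#' Write a run set as TSV (and optionally BED)
#'
#' @param runset a `run_set`.
#' @param path output TSV path; columns sample, population, kind, chrom,
#'   start_bp, end_bp, n_snp, length_bp, class.
#' @param bed_path optional BED output (0-based half-open).
#' @export
write_runs <- function(runset, path, bed_path = NULL) {
  r <- runset$runs
  out <- data.frame(sample = r$sample_id, population = r$population,
                    kind = r$kind, chrom = r$chrom, start_bp = r$start_bp,
                    end_bp = r$end_bp, n_snp = r$n_snp,
                    length_bp = r$length_bp, class = as.character(r$length_class))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(r$chrom, format(r$start_bp - 1, scientific = FALSE, trim = TRUE),
                      format(r$end_bp, scientific = FALSE, trim = TRUE),
                      paste(r$sample_id, r$kind, sep = "_"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
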