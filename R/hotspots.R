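#' Per-SNP run-incidence track
#'
#' For every marker and population: the number of samples whose run (ROH or
#' ROHet) covers the marker position, the number of samples genotyped at
#' the marker, and their ratio - the incidence fraction the hotspot
#' thresholds act on. A marker is inside a run when
#' `start_bp <= position <= end_bp`.
#'
#' @param runset a `run_set`.
#' @param dataset the [genotype_dataset()] sharing the run set's marker map.
#' @param populations which populations to compute (default: all in the
#'   dataset).
#' @return data.frame: `population`, `kind`, `chrom`, `pos_bp`,
#'   `marker_id`, `n_in_run`, `n_genotyped`, `fraction`.
#' @export
incidence_track <- function(runset, dataset, populations = NULL) {
  stopifnot(inherits(runset, "run_set"), inherits(dataset, "genotype_dataset"))
  map <- dataset$map
  runs <- runset$runs
  if (is.null(populations)) populations <- unique(dataset$samples$population)
  out <- list()
  for (pp in populations) {
    rows_p <- which(dataset$samples$population == pp)
    n_geno <- colSums(!is.na(dataset$genotypes[rows_p, , drop = FALSE]))
    n_in <- integer(nrow(map))
    rr <- runs[runs$population == pp, , drop = FALSE]
    for (chr in unique(rr$chrom)) {
      mi <- which(map$chrom == chr)
      pos <- map$pos_bp[mi]
      rc <- rr[rr$chrom == chr, , drop = FALSE]
      # difference-array accumulation of covering runs per marker
      lo <- findInterval(rc$start_bp - 0.5, pos) + 1L
      hi <- findInterval(rc$end_bp + 0.5, pos)
      ok <- lo <= hi
      d <- integer(length(mi) + 1L)
      for (k in which(ok)) {
        d[lo[k]] <- d[lo[k]] + 1L
        d[hi[k] + 1L] <- d[hi[k] + 1L] - 1L
      }
      n_in[mi] <- cumsum(d[seq_along(mi)])
    }
    out[[pp]] <- data.frame(population = pp, kind = runset$kind,
                            chrom = map$chrom, pos_bp = map$pos_bp,
                            marker_id = map$marker_id,
                            n_in_run = n_in, n_genotyped = n_geno,
                            fraction = ifelse(n_geno > 0, n_in / n_geno, 0),
                            row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Hotspot threshold specification
#'
#' Three modes resolve the incidence fraction above which a SNP counts as a
#' hotspot SNP: `absolute` uses `value` directly (e.g. 0.50 - at least half
#' the population in a run); `top_quantile` uses the `(1 - value)` quantile
#' of the per-marker incidence distribution (e.g. `value = 0.005` keeps the
#' top 0.5%); `combined` takes the maximum of the two resolved fractions
#' (the default for ROH, where an "at least 50%" rule and a top-quantile
#' rule are both in common use; for ROHet the usual choice is
#' `top_quantile` with `value = 0.001`).
#'
#' @param mode `"absolute"`, `"top_quantile"` or `"combined"`.
#' @param value threshold fraction (absolute) or tail probability
#'   (top_quantile).
#' @param absolute_value the absolute component of `combined` mode.
#' @return a `threshold_spec` list.
#' @export
threshold_spec <- function(mode = c("absolute", "top_quantile", "combined"),
                           value, absolute_value = 0.5) {
  mode <- match.arg(mode)
  stopifnot(value > 0, value < 1)
  structure(list(mode = mode, value = value, absolute_value = absolute_value),
            class = "threshold_spec")
}

#' Resolve a hotspot threshold against an incidence track
#'
#' In `top_quantile` mode the resolved fraction is the empirical top-tail
#' cutoff: the `ceiling(q * m)`-th largest per-marker fraction on an
#' m-marker track, so that (up to ties, which are included downstream)
#' exactly the top `q` share of markers reaches it. On a track of 999
#' zeros and a single 1.0, a 0.1% tail therefore resolves to 1.0.
#'
#' @param track output of [incidence_track()] (one population).
#' @param spec a [threshold_spec()].
#' @return the resolved fraction actually applied (scalar).
#' @export
resolve_threshold <- function(track, spec) {
  stopifnot(inherits(spec, "threshold_spec"), nrow(track) > 0)
  q <- function(tail) {
    k <- min(nrow(track), max(1L, ceiling(tail * nrow(track))))
    sort(track$fraction, decreasing = TRUE)[k]
  }
  switch(spec$mode,
         absolute = spec$value,
         top_quantile = q(spec$value),
         combined = max(spec$absolute_value, q(spec$value)))
}

#' Call hotspot islands from an incidence track
#'
#' Markers whose incidence fraction is at least the resolved threshold
#' (ties included) are hotspot SNPs; consecutive hotspot SNPs on a
#' chromosome separated by at most `merge_gap_bp` merge into one island.
#' Island bounds are the positions of the first and last member SNP.
#'
#' @param track output of [incidence_track()] for one population.
#' @param spec a [threshold_spec()], or a numeric resolved fraction.
#' @param merge_gap_bp merge distance, default 500 kb (the run gap rule).
#' @return data.frame of islands: `population`, `kind`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snp`, `peak_fraction`, `mean_fraction`,
#'   `resolved_threshold`. Zero rows when nothing exceeds the threshold.
#' @export
call_islands <- function(track, spec, merge_gap_bp = 5e5) {
  stopifnot(length(unique(track$population)) <= 1)
  thr <- if (is.numeric(spec)) spec else resolve_threshold(track, spec)
  hot <- track[track$fraction >= thr, , drop = FALSE]
  empty <- data.frame(population = character(0), kind = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snp = integer(0),
                      peak_fraction = numeric(0), mean_fraction = numeric(0),
                      resolved_threshold = numeric(0))
  if (!nrow(hot)) return(empty)
  out <- list()
  for (chr in unique(hot$chrom)) {
    h <- hot[hot$chrom == chr, , drop = FALSE]
    h <- h[order(h$pos_bp), , drop = FALSE]
    grp <- cumsum(c(1, diff(h$pos_bp) > merge_gap_bp))
    for (g in unique(grp)) {
      hg <- h[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        population = hg$population[1], kind = hg$kind[1], chrom = chr,
        start_bp = min(hg$pos_bp), end_bp = max(hg$pos_bp),
        n_snp = nrow(hg), peak_fraction = max(hg$fraction),
        mean_fraction = mean(hg$fraction), resolved_threshold = thr)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cross-population island overlaps
#'
#' Intersects island intervals across populations (per chromosome and run
#' kind) and reports every maximal genomic region covered by islands of at
#' least `min_populations` populations, with the contributing population
#' set.
#'
#' @param islands data.frame of islands from [call_islands()] (rows may mix
#'   populations), or a list of such data.frames.
#' @param min_populations minimum populations sharing a region (default 2).
#' @return data.frame: `kind`, `chrom`, `start_bp`, `end_bp`,
#'   `n_populations`, `populations` (comma-separated, sorted).
#' @export
overlap_islands <- function(islands, min_populations = 2) {
  if (is.list(islands) && !is.data.frame(islands)) {
    islands <- do.call(rbind, islands)
  }
  empty <- data.frame(kind = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_populations = integer(0), populations = character(0))
  if (is.null(islands) || !nrow(islands)) return(empty)
  if (length(unique(islands$population)) < 2) return(empty)
  out <- list()
  for (kd in unique(islands$kind)) {
    for (chr in unique(islands$chrom[islands$kind == kd])) {
      isl <- islands[islands$kind == kd & islands$chrom == chr, , drop = FALSE]
      ir <- IRanges::IRanges(start = isl$start_bp, end = isl$end_bp)
      dj <- IRanges::disjoin(ir)
      ov <- IRanges::findOverlaps(dj, ir)
      pops_per <- split(isl$population[S4Vectors::subjectHits(ov)],
                        S4Vectors::queryHits(ov))
      for (k in seq_along(dj)) {
        pops <- sort(unique(pops_per[[as.character(k)]]))
        if (length(pops) >= min_populations) {
          out[[length(out) + 1L]] <- data.frame(
            kind = kd, chrom = chr,
            start_bp = IRanges::start(dj)[k], end_bp = IRanges::end(dj)[k],
            n_populations = length(pops),
            populations = paste(pops, collapse = ","))
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # merge adjacent pieces sharing the same population set
  res <- res[order(res$kind, res$chrom, res$start_bp), , drop = FALSE]
  keep <- logical(nrow(res)); keep[1] <- TRUE; j <- 1
  for (i in seq_len(nrow(res))[-1]) {
    if (res$kind[i] == res$kind[j] && res$chrom[i] == res$chrom[j] &&
        res$populations[i] == res$populations[j] &&
        res$start_bp[i] <= res$end_bp[j] + 1) {
      res$end_bp[j] <- max(res$end_bp[j], res$end_bp[i])
    } else {
      j <- i; keep[i] <- TRUE
    }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate islands against a user-supplied interval file
#'
#' Reads a BED (0-based half-open) or GFF3 (1-based inclusive) interval
#' file - coordinate conversion to 1-based inclusive is handled by the
#' importer - and reports every feature overlapping each island by at least
#' 1 bp, with the overlap length.
#'
#' @param islands data.frame from [call_islands()].
#' @param annotation_path path to a `.bed`, `.gff`/`.gff3` (or `.gtf`)
#'   file.
#' @return data.frame: island columns (`population`, `kind`, `chrom`,
#'   `start_bp`, `end_bp`) plus `feature`, `feature_start`, `feature_end`,
#'   `overlap_bp`; zero rows if the annotation is empty or nothing
#'   overlaps.
#' @export
annotate_islands <- function(islands, annotation_path) {
  stopifnot(file.exists(annotation_path))
  empty <- data.frame(population = character(0), kind = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), feature = character(0),
                      feature_start = numeric(0), feature_end = numeric(0),
                      overlap_bp = numeric(0))
  if (!nrow(islands)) return(empty)
  feats <- tryCatch(rtracklayer::import(annotation_path),
                    error = function(e) NULL)
  if (is.null(feats) || !length(feats)) return(empty)
  fd <- as.data.frame(feats)
  name_col <- intersect(c("name", "Name", "ID", "gene_id"), names(fd))
  fname <- if (length(name_col)) as.character(fd[[name_col[1]]]) else
    paste0("feature_", seq_len(nrow(fd)))
  fname[is.na(fname)] <- paste0("feature_", which(is.na(fname)))
  out <- list()
  for (i in seq_len(nrow(islands))) {
    sel <- as.character(fd$seqnames) == as.character(islands$chrom[i]) &
      fd$end >= islands$start_bp[i] & fd$start <= islands$end_bp[i]
    if (!any(sel)) next
    w <- which(sel)
    out[[length(out) + 1L]] <- data.frame(
      population = islands$population[i], kind = islands$kind[i],
      chrom = islands$chrom[i], start_bp = islands$start_bp[i],
      end_bp = islands$end_bp[i], feature = fname[w],
      feature_start = fd$start[w], feature_end = fd$end[w],
      overlap_bp = pmin(fd$end[w], islands$end_bp[i]) -
        pmax(fd$start[w], islands$start_bp[i]) + 1)
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
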