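#' Per-marker allele frequencies and genotype counts
#'
#' Frequency of the A2 allele per marker, computed over called genotypes
#' only: `p = (n_het + 2 n_hom2) / (2 n_called)`. Markers with zero called
#' genotypes get `NA` frequency and are flagged.
#'
#' @param dataset a [genotype_dataset()], or a dosage matrix.
#' @return data.frame with columns `marker_id` (if available), `n_hom1`,
#'   `n_het`, `n_hom2`, `n_missing`, `n_called`, `p`.
#' @export
allele_frequencies <- function(dataset) {
  G <- if (inherits(dataset, "genotype_dataset")) dataset$genotypes else as.matrix(dataset)
  n_hom1 <- colSums(G == 0L, na.rm = TRUE)
  n_het  <- colSums(G == 1L, na.rm = TRUE)
  n_hom2 <- colSums(G == 2L, na.rm = TRUE)
  n_missing <- colSums(is.na(G))
  n_called <- n_hom1 + n_het + n_hom2
  p <- ifelse(n_called > 0, (n_het + 2 * n_hom2) / (2 * n_called), NA_real_)
  out <- data.frame(n_hom1 = n_hom1, n_het = n_het, n_hom2 = n_hom2,
                    n_missing = n_missing, n_called = n_called, p = p,
                    row.names = NULL)
  if (inherits(dataset, "genotype_dataset")) {
    out <- cbind(marker_id = dataset$map$marker_id, out)
  }
  out
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test on one marker's genotype counts: the p-value sums,
#' over the conditional distribution of the heterozygote count given the
#' allele counts, the probabilities of all configurations no more likely
#' than the observed one (the standard exact test, no mid-p correction).
#' Probabilities are built by the usual ratio recurrence from the modal
#' heterozygote count, which is numerically stable for large samples.
#' Monomorphic markers return 1 by convention.
#'
#' @param n_hom1,n_het,n_hom2 non-negative integer genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("total genotype count must be >= 1")
  n_a <- 2 * n_hom1 + n_het          # minor-side allele count (either side works)
  n_b <- 2 * n_hom2 + n_het
  if (n_a == 0 || n_b == 0) return(1.0)
  rare <- min(n_a, n_b)
  # feasible heterozygote counts share the parity of the rare allele count
  h_vals <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(h_vals))
  # start from an interior value and apply the ratio recurrence both ways:
  # P(h+2)/P(h) = 4 * n1(h) * n2(h) / ((h+2)(h+1)) with n1, n2 the hom counts
  h0_idx <- which.min(abs(h_vals - rare / 2))
  probs[h0_idx] <- 1
  hom_r <- function(h) (rare - h) / 2          # homs of the rarer allele
  hom_c <- function(h) (2 * n - rare - h) / 2  # homs of the commoner allele
  if (h0_idx < length(h_vals)) {
    for (k in h0_idx:(length(h_vals) - 1)) {
      h <- h_vals[k]
      probs[k + 1] <- probs[k] * 4 * hom_r(h) * hom_c(h) / ((h + 2) * (h + 1))
    }
  }
  if (h0_idx > 1) {
    for (k in h0_idx:2) {
      h <- h_vals[k]
      probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (hom_r(h) + 1) * (hom_c(h) + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, h_vals)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Quality-control configuration
#'
#' Two QC tracks are supported. The `strict` track (used for relationship,
#' inbreeding-from-genotypes and structure analyses) applies, in order:
#' call-quality score, marker call rate, sample call rate, minor allele
#' frequency and a Hardy-Weinberg exact-test cut. The `lenient` track (used
#' for run detection, where rare and monomorphic markers are informative)
#' disables the MAF and HWE filters.
#'
#' @param track `"strict"` or `"lenient"`.
#' @param maf_min minimum minor allele frequency (strict only), default 0.05.
#' @param hwe_p_min minimum HWE exact p-value (strict only), default 1e-5.
#' @param marker_call_rate_min,sample_call_rate_min minimum call rates,
#'   default 0.90 each.
#' @param quality_score_min minimum per-marker quality score, default 0.60;
#'   applied only when the map carries a `quality` column.
#' @return a `qc_config` list.
#' @export
qc_config <- function(track = c("strict", "lenient"), maf_min = 0.05,
                      hwe_p_min = 1e-5, marker_call_rate_min = 0.90,
                      sample_call_rate_min = 0.90, quality_score_min = 0.60) {
  track <- match.arg(track)
  thresholds <- c(maf_min = maf_min, hwe_p_min = hwe_p_min,
                  marker_call_rate_min = marker_call_rate_min,
                  sample_call_rate_min = sample_call_rate_min,
                  quality_score_min = quality_score_min)
  if (any(thresholds < 0 | thresholds > 1)) stop("all QC thresholds must be in [0,1]")
  structure(list(track = track, maf_min = maf_min, hwe_p_min = hwe_p_min,
                 marker_call_rate_min = marker_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min,
                 quality_score_min = quality_score_min),
            class = "qc_config")
}

#' Apply quality control to a genotype dataset
#'
#' Filters are applied in a fixed order so that the report is deterministic:
#' non-autosomal markers are dropped first, then (markers) quality score,
#' marker call rate, then sample call rate (computed on the surviving
#' markers), then - on the strict track only - MAF and the HWE exact test
#' (on pooled counts of the surviving samples).
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [qc_config()].
#' @return list with elements `dataset` (filtered) and `report` (a
#'   `qc_report`: per-filter removal counts in application order plus
#'   retained ids).
#' @export
apply_qc <- function(dataset, config = qc_config()) {
  stopifnot(inherits(dataset, "genotype_dataset"), inherits(config, "qc_config"))
  steps <- data.frame(filter = character(0), unit = character(0),
                      removed = integer(0), remaining = integer(0))
  log_step <- function(filter, unit, removed, remaining) {
    rbind(steps, data.frame(filter = filter, unit = unit,
                            removed = as.integer(removed),
                            remaining = as.integer(remaining)))
  }
  ds <- dataset

  keep <- ds$map$chrom %in% AUTOSOMES
  steps <- log_step("non_autosomal", "marker", sum(!keep), sum(keep))
  ds <- subset_dataset(ds, markers = keep)

  if (!is.null(ds$map$quality)) {
    keep <- !is.na(ds$map$quality) & ds$map$quality >= config$quality_score_min
    steps <- log_step("quality_score", "marker", sum(!keep), sum(keep))
    ds <- subset_dataset(ds, markers = keep)
  }

  n <- nrow(ds$genotypes)
  call_rate_m <- 1 - colSums(is.na(ds$genotypes)) / max(1, n)
  keep <- call_rate_m >= config$marker_call_rate_min
  steps <- log_step("marker_call_rate", "marker", sum(!keep), sum(keep))
  ds <- subset_dataset(ds, markers = keep)
  if (!ncol(ds$genotypes)) stop("QC removed all markers")

  m <- ncol(ds$genotypes)
  call_rate_s <- 1 - rowSums(is.na(ds$genotypes)) / m
  keep <- call_rate_s >= config$sample_call_rate_min
  steps <- log_step("sample_call_rate", "sample", sum(!keep), sum(keep))
  ds <- subset_dataset(ds, samples = keep)
  if (!nrow(ds$genotypes)) stop("QC removed all samples")

  if (config$track == "strict") {
    fr <- allele_frequencies(ds)
    maf <- pmin(fr$p, 1 - fr$p)
    keep <- !is.na(maf) & maf >= config$maf_min
    steps <- log_step("maf", "marker", sum(!keep), sum(keep))
    ds <- subset_dataset(ds, markers = keep)
    fr <- fr[keep, , drop = FALSE]

    hwe_p <- mapply(hwe_exact_test, fr$n_hom1, fr$n_het, fr$n_hom2)
    keep <- hwe_p > config$hwe_p_min
    steps <- log_step("hwe", "marker", sum(!keep), sum(keep))
    ds <- subset_dataset(ds, markers = keep)
  }
  if (!ncol(ds$genotypes)) stop("QC removed all markers")

  report <- structure(list(track = config$track, steps = steps,
                           n_markers_in = ncol(dataset$genotypes),
                           n_samples_in = nrow(dataset$genotypes),
                           markers_retained = ds$map$marker_id,
                           samples_retained = ds$samples$sample_id),
                      class = "qc_report")
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$track, " track): ", x$n_samples_in, " samples x ",
      x$n_markers_in, " markers in -> ", length(x$samples_retained),
      " x ", length(x$markers_retained), " retained\n", sep = "")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
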