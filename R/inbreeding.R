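#' ROH-based inbreeding coefficient, total and per length class
#'
#' F_ROH for a sample is the summed length of its ROH divided by the total
#' autosomal length covered by the marker map (L_TOTAL, see
#' [genome_extent()]); the class-wise variants restrict the numerator to
#' runs of one length class, so the class values sum exactly to the total.
#' Samples in `samples` without any run get 0.
#'
#' @param runset a `run_set` of kind `"ROH"`.
#' @param extent L_TOTAL in bp, from [genome_extent()] on the same marker
#'   set that the runs were called on.
#' @param samples optional data.frame (`sample_id`, `population`) of all
#'   samples (zero-run samples get F_ROH = 0); defaults to samples present
#'   in the run set.
#' @return data.frame: `sample_id`, `population`, `f_roh_total`, one
#'   `f_roh_<class>` column per length class.
#' @export
f_roh <- function(runset, extent, samples = NULL) {
  stopifnot(inherits(runset, "run_set"), runset$kind == "ROH", extent > 0)
  runs <- runset$runs
  if (is.null(samples)) samples <- unique(runs[, c("sample_id", "population")])
  classes <- levels(runs$length_class)
  out <- data.frame(sample_id = as.character(samples$sample_id),
                    population = as.character(samples$population),
                    stringsAsFactors = FALSE)
  cls_cols <- paste0("f_roh_",
                     gsub("^_+|_+$", "", gsub("[^0-9A-Za-z.]+", "_", classes)))
  for (k in seq_along(classes)) {
    out[[cls_cols[k]]] <- vapply(out$sample_id, function(s)
      sum(runs$length_bp[runs$sample_id == s &
                         as.character(runs$length_class) == classes[k]]) / extent,
      numeric(1))
  }
  out$f_roh_total <- rowSums(out[, cls_cols, drop = FALSE])
  out[, c("sample_id", "population", "f_roh_total", cls_cols)]
}

#' VanRaden genomic relationship matrix and F_G
#'
#' Method-1 G: dosages are column-centered by twice the allele frequency
#' (`Z = M - 2p`) and `G = Z Z' / (2 * sum p (1 - p))`. Missing genotypes
#' are imputed to the column mean `2p` (contributing zero after centering).
#' The per-sample genomic inbreeding coefficient is the diagonal minus one,
#' `F_G = G_ii - 1`. Monomorphic markers carry no information and are
#' excluded from both Z and the scaling constant (with a warning).
#'
#' With `center = FALSE` the literal uncentered cross-product of 0/1/2
#' dosages is returned for comparison; its diagonal has no `F = G_ii - 1`
#' interpretation.
#'
#' @param dataset a [genotype_dataset()] (strict-QC marker set).
#' @param freqs optional vector of A2 frequencies to use (default: computed
#'   from the dataset, pooled over populations).
#' @param center use VanRaden centering (default TRUE).
#' @return list: `G` (n x n), `f_g` (named vector), `p` (frequencies used),
#'   `scale` (2 sum p(1-p)).
#' @export
grm_vanraden <- function(dataset, freqs = NULL, center = TRUE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  G0 <- dataset$genotypes
  p <- if (is.null(freqs)) allele_frequencies(dataset)$p else freqs
  mono <- is.na(p) | p <= 0 | p >= 1
  if (all(mono)) stop("all markers monomorphic: zero scaling constant")
  if (any(mono)) {
    warning(sum(mono), " monomorphic marker(s) excluded from G")
    G0 <- G0[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  M <- G0
  storage.mode(M) <- "double"
  for (j in which(colSums(is.na(M)) > 0)) {
    M[is.na(M[, j]), j] <- 2 * p[j]
  }
  denom <- 2 * sum(p * (1 - p))
  Z <- if (center) sweep(M, 2, 2 * p) else M
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(dataset$samples$sample_id, dataset$samples$sample_id)
  list(G = G, f_g = diag(G) - 1, p = p, scale = denom)
}

#' Excess-homozygosity inbreeding coefficient F_exH
#'
#' Per sample, over its called autosomal genotypes:
#' `F_exH = (Obs_homo - Exp_homo) / (Total_observation - Exp_homo)`, where
#' `Obs_homo` counts homozygous calls, `Total_observation` counts called
#' genotypes, and `Exp_homo = sum_j (1 - 2 p_j (1 - p_j) n_j / (n_j - 1))`
#' uses the bias-corrected expected homozygosity at each of the sample's
#' called markers (`p_j`, `n_j`: pooled sample frequency and called-sample
#' count at marker j). Markers with `n_j <= 1` or undefined frequency are
#' excluded.
#'
#' @param dataset a [genotype_dataset()] (strict-QC marker set).
#' @param freqs optional frequency vector overriding the pooled estimate.
#' @return data.frame: `sample_id`, `population`, `obs_homo`, `exp_homo`,
#'   `total_observation`, `f_exh`.
#' @export
f_exh <- function(dataset, freqs = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  G <- dataset$genotypes
  fr <- allele_frequencies(dataset)
  p <- if (is.null(freqs)) fr$p else freqs
  usable <- !is.na(p) & fr$n_called > 1
  exp_homo_j <- ifelse(usable,
                       1 - 2 * p * (1 - p) * fr$n_called / (fr$n_called - 1),
                       NA_real_)
  called <- !is.na(G)
  called[, !usable] <- FALSE
  hom <- called & (G == 0L | G == 2L)
  obs <- rowSums(hom, na.rm = TRUE)
  tot <- rowSums(called)
  expd <- as.numeric(called %*% ifelse(usable, exp_homo_j, 0))
  f <- ifelse(tot - expd != 0, (obs - expd) / (tot - expd), 0)
  data.frame(sample_id = dataset$samples$sample_id,
             population = dataset$samples$population,
             obs_homo = obs, exp_homo = expd, total_observation = tot,
             f_exh = f, row.names = NULL)
}

#' ROHet-based heterozygosity coefficient
#'
#' Default definition: summed ROHet length over L_TOTAL (the mirror image
#' of F_ROH). The alternative definition - the fraction of the sample's
#' markers lying inside a ROHet - is available via
#' `definition = "snp_fraction"`; the two agree in ranking but not in
#' magnitude. Neither is presented as a certified published formula: the
#' source literature is ambiguous about which is meant.
#'
#' @param runset a `run_set` of kind `"ROHet"`.
#' @param extent L_TOTAL in bp (for `"length_fraction"`).
#' @param dataset a [genotype_dataset()] (needed for `"snp_fraction"`).
#' @param samples optional full sample sheet as in [f_roh()].
#' @param definition `"length_fraction"` (default) or `"snp_fraction"`.
#' @return data.frame: `sample_id`, `population`, `het_coefficient`.
#' @export
het_coefficient <- function(runset, extent = NULL, dataset = NULL,
                            samples = NULL,
                            definition = c("length_fraction", "snp_fraction")) {
  stopifnot(inherits(runset, "run_set"), runset$kind == "ROHet")
  definition <- match.arg(definition)
  runs <- runset$runs
  if (is.null(samples)) samples <- unique(runs[, c("sample_id", "population")])
  ids <- as.character(samples$sample_id)
  if (definition == "length_fraction") {
    stopifnot(!is.null(extent), extent > 0)
    val <- vapply(ids, function(s)
      sum(runs$length_bp[runs$sample_id == s]) / extent, numeric(1))
  } else {
    stopifnot(!is.null(dataset))
    m <- ncol(dataset$genotypes)
    val <- vapply(ids, function(s)
      sum(runs$n_snp[runs$sample_id == s]) / m, numeric(1))
  }
  data.frame(sample_id = ids, population = as.character(samples$population),
             het_coefficient = as.numeric(val), row.names = NULL)
}

#' Assemble the per-sample inbreeding table
#'
#' Joins the coefficients of [f_roh()], [grm_vanraden()], [f_exh()] and
#' [het_coefficient()] into one row per sample.
#'
#' @param froh output of [f_roh()].
#' @param grm output of [grm_vanraden()].
#' @param fexh output of [f_exh()].
#' @param hetc optional output of [het_coefficient()].
#' @return data.frame, one row per sample.
#' @export
inbreeding_table <- function(froh, grm, fexh, hetc = NULL) {
  out <- froh
  out$f_g <- as.numeric(grm$f_g[match(out$sample_id, names(grm$f_g))])
  i <- match(out$sample_id, fexh$sample_id)
  out$f_exh <- fexh$f_exh[i]
  out$obs_homo <- fexh$obs_homo[i]
  out$exp_homo <- fexh$exp_homo[i]
  out$total_observation <- fexh$total_observation[i]
  if (!is.null(hetc)) {
    out$het_coefficient <- hetc$het_coefficient[match(out$sample_id,
                                                      hetc$sample_id)]
  }
  out
}

#' Pearson correlations among inbreeding coefficients
#'
#' Symmetric Pearson correlation matrix over the coefficient columns of an
#' inbreeding table, with two-sided t-test p-values.
#'
#' @param table data.frame from [inbreeding_table()] (or any data.frame of
#'   numeric coefficient columns plus `sample_id`).
#' @param columns which columns to correlate; default: every numeric column
#'   except the count columns.
#' @return list: `r` (correlation matrix, unit diagonal), `p_value`
#'   (matrix, NA diagonal), `n` (samples used).
#' @export
inbreeding_correlations <- function(table, columns = NULL) {
  if (is.null(columns)) {
    num <- vapply(table, is.numeric, logical(1))
    columns <- setdiff(names(table)[num],
                       c("obs_homo", "exp_homo", "total_observation"))
  }
  X <- as.matrix(table[, columns, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 samples for correlations")
  constant <- apply(X, 2, stats::sd) == 0
  if (any(constant)) {
    message("dropping constant column(s) from correlation matrix: ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }
  r <- stats::cor(X)
  k <- ncol(X)
  pm <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pv <- if (stats::sd(X[, i]) == 0 || stats::sd(X[, j]) == 0) NA_real_ else
        stats::cor.test(X[, i], X[, j])$p.value
      pm[i, j] <- pm[j, i] <- pv
    }
  }
  diag(r) <- 1
  list(r = r, p_value = pm, n = nrow(X))
}
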