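#' Per-population diversity summary
#'
#' Observed heterozygosity `Ho` (mean over markers of the heterozygote
#' fraction among called samples), expected heterozygosity `He` (mean of
#' `2p(1-p)`, multiplied by `n/(n-1)` when `unbiased = TRUE`), and the
#' proportion of polymorphic markers `PN` (markers with `0 < p < 1` inside
#' the population). Markers with no called genotype in a population are
#' skipped.
#'
#' @param dataset a [genotype_dataset()] (strict-QC marker set).
#' @param unbiased apply the small-sample correction to He.
#' @return data.frame: `population`, `n_samples`, `ho`, `he`, `pn`.
#' @export
diversity_summary <- function(dataset, unbiased = FALSE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  pops <- unique(dataset$samples$population)
  rows <- lapply(pops, function(pp) {
    ds <- subset_dataset(dataset, samples = dataset$samples$population == pp)
    fr <- allele_frequencies(ds)
    ok <- fr$n_called > 0
    ho_j <- fr$n_het[ok] / fr$n_called[ok]
    he_j <- 2 * fr$p[ok] * (1 - fr$p[ok])
    if (unbiased) {
      ok2 <- fr$n_called[ok] > 1
      he_j <- he_j * ifelse(ok2, fr$n_called[ok] / (fr$n_called[ok] - 1), NA)
    }
    data.frame(population = pp, n_samples = nrow(ds$genotypes),
               ho = mean(ho_j), he = mean(he_j, na.rm = TRUE),
               pn = mean(fr$p[ok] > 0 & fr$p[ok] < 1))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Identity-by-state genetic distances
#'
#' `d(i, j) = 1 - mean over mutually called markers of (shared alleles)/2`,
#' where the shared-allele count between dosages a and b is `2 - |a - b|`.
#' Missing genotypes are handled by pairwise deletion. `method = "hamming"`
#' instead returns the mean absolute dosage difference divided by 2 (the
#' allele-count Hamming distance), which differs from `1 - IBS` only in how
#' double differences (0 vs 2) are weighted relative to single ones -
#' identical here, so the two coincide; both are kept for interface parity
#' with common pipelines.
#'
#' @param dataset a [genotype_dataset()].
#' @param method `"ibs"` (default) or `"hamming"`.
#' @return symmetric n x n distance matrix, zero diagonal, sample ids as
#'   dimnames.
#' @export
ibs_distance <- function(dataset, method = c("ibs", "hamming")) {
  method <- match.arg(method)
  G <- dataset$genotypes
  n <- nrow(G)
  stopifnot(n >= 2)
  storage.mode(G) <- "double"
  called <- !is.na(G)
  G0 <- G; G0[!called] <- 0
  # sum |a - b| over mutually called markers, via the identity
  # |a-b| = a + b - 2*min(a,b); with dosages 0/1/2, min(a,b) decomposes on
  # indicators a>=1,b>=1 and a==2,b==2.
  A1 <- (G0 >= 1) & called; A2 <- (G0 == 2) & called
  Sa <- tcrossprod(G0 * called, 1 * called)   # sum over mutual of a
  Sb <- t(Sa)
  Smin <- tcrossprod(1 * A1) + tcrossprod(1 * A2)
  absdiff <- Sa + Sb - 2 * Smin
  nmut <- tcrossprod(1 * called)
  if (any(nmut[upper.tri(nmut)] == 0)) {
    w <- which(nmut == 0 & upper.tri(nmut), arr.ind = TRUE)[1, ]
    stop("no mutually called markers for pair ",
         dataset$samples$sample_id[w[1]], " / ",
         dataset$samples$sample_id[w[2]])
  }
  D <- absdiff / (2 * nmut)
  diag(D) <- 0
  dimnames(D) <- list(dataset$samples$sample_id, dataset$samples$sample_id)
  D
}

#' Population-mean distance matrix
#'
#' Mean between-population sample distances, for population-level trees.
#'
#' @param dist_matrix sample-level distance matrix from [ibs_distance()].
#' @param populations population label per sample (in matrix order).
#' @return k x k symmetric matrix, zero diagonal.
#' @export
population_distance <- function(dist_matrix, populations) {
  pops <- unique(populations)
  k <- length(pops)
  PD <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      PD[i, j] <- mean(dist_matrix[populations == pops[i],
                                   populations == pops[j]])
    }
  }
  PD
}

#' Principal component analysis of the dosage matrix
#'
#' Missing genotypes are imputed to the column mean (2p); columns are then
#' centered (and optionally standardized) and the sample coordinates,
#' eigenvalues and per-component variance percentages are returned from the
#' singular value decomposition.
#'
#' @param dataset a [genotype_dataset()] (strict-QC marker set).
#' @param k number of components (default `min(n, m) - 1`).
#' @param standardize divide columns by their standard deviation.
#' @return list: `coordinates` (n x k), `eigenvalues`, `variance_pct`.
#' @export
pca_genotypes <- function(dataset, k = NULL, standardize = FALSE) {
  G <- dataset$genotypes
  storage.mode(G) <- "double"
  n <- nrow(G)
  cm <- colMeans(G, na.rm = TRUE)
  for (j in which(colSums(is.na(G)) > 0)) G[is.na(G[, j]), j] <- cm[j]
  X <- sweep(G, 2, colMeans(G))
  if (standardize) {
    sdv <- apply(X, 2, stats::sd)
    X <- sweep(X, 2, ifelse(sdv > 0, sdv, 1), "/")
  }
  kmax <- min(n - 1, ncol(X))
  if (is.null(k)) k <- kmax
  stopifnot(k >= 1, k <= kmax)
  sv <- svd(X, nu = kmax, nv = 0)
  eig <- sv$d[seq_len(kmax)]^2 / (n - 1)
  coords <- sv$u %*% diag(sv$d[seq_len(kmax)], kmax)
  rownames(coords) <- dataset$samples$sample_id
  colnames(coords) <- paste0("PC", seq_len(kmax))
  list(coordinates = coords[, seq_len(k), drop = FALSE],
       eigenvalues = eig,
       variance_pct = 100 * eig / sum(eig))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`). Optionally, negative branch
#' lengths - which arise on non-additive matrices - are clamped to zero
#' with the deficit moved onto the branches adjacent at the same node, so
#' path lengths through the node are preserved; the tree is flagged when
#' this happens. Round-trips losslessly through Newick.
#'
#' @param dist_matrix symmetric distance matrix (n >= 3) with labels.
#' @param clamp_negative apply the negative-branch correction.
#' @return an `ape::phylo` tree; attribute `negative_branches` gives the
#'   number of clamped branches.
#' @export
nj_tree <- function(dist_matrix, clamp_negative = TRUE) {
  stopifnot(nrow(dist_matrix) >= 3, isTRUE(all.equal(dist_matrix,
                                                     t(dist_matrix))))
  tree <- ape::nj(stats::as.dist(dist_matrix))
  n_neg <- sum(tree$edge.length < 0)
  if (clamp_negative && n_neg > 0) {
    for (e in which(tree$edge.length < 0)) {
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      child <- tree$edge[e, 2]
      adj <- which(tree$edge[, 1] == child)
      tree$edge.length[adj] <- tree$edge.length[adj] + deficit
    }
  }
  attr(tree, "negative_branches") <- n_neg
  tree
}

#' Write a tree in Newick format
#'
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
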