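#' @keywords internal
"_PACKAGE"

AUTOSOMES <- as.character(1:29)

#' Construct a marker map
#'
#' A marker map describes the SNP panel: one row per marker with chromosome
#' label, marker identifier and 1-based physical position. Positions must be
#' strictly increasing within each chromosome and markers are stored grouped
#' by chromosome in map order. An optional per-marker `quality` column (a
#' call-quality score in \[0, 1\], the role a chip GenCall score plays) can be
#' carried for quality filtering.
#'
#' @param chrom character or integer vector of chromosome labels. Autosomes
#'   are the labels `"1"`..`"29"`; any other label (e.g. `"X"`, `"0"`) is kept
#'   in the map but dropped at QC time.
#' @param marker_id character vector of unique marker names.
#' @param pos_bp integer vector of 1-based physical positions.
#' @param quality optional numeric vector in \[0, 1\].
#' @param a1,a2 optional character vectors of reference alleles; dosage counts
#'   copies of `a2`.
#' @return a `data.frame` of class `marker_map`.
#' @export
marker_map <- function(chrom, marker_id, pos_bp, quality = NULL,
                       a1 = NULL, a2 = NULL) {
  chrom <- as.character(chrom)
  n <- length(chrom)
  stopifnot(length(marker_id) == n, length(pos_bp) == n)
  if (anyDuplicated(marker_id)) {
    stop("duplicate marker ids: ",
         paste(unique(marker_id[duplicated(marker_id)])[1:min(3, n)],
               collapse = ", "))
  }
  if (any(pos_bp < 1)) stop("marker positions must be >= 1")
  map <- data.frame(chrom = chrom, marker_id = as.character(marker_id),
                    pos_bp = as.integer(pos_bp), stringsAsFactors = FALSE)
  if (!is.null(quality)) {
    stopifnot(length(quality) == n, all(quality >= 0 & quality <= 1, na.rm = TRUE))
    map$quality <- as.numeric(quality)
  }
  if (!is.null(a1)) map$a1 <- as.character(a1)
  if (!is.null(a2)) map$a2 <- as.character(a2)
  # group by chromosome (order of first appearance), positions sorted within
  chrom_levels <- unique(map$chrom)
  ord <- order(match(map$chrom, chrom_levels), map$pos_bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  by_chr <- split(map$pos_bp, map$chrom)
  bad <- names(by_chr)[vapply(by_chr, function(p) any(diff(p) <= 0), logical(1))]
  if (length(bad)) {
    stop("positions not strictly increasing on chromosome(s): ",
         paste(bad, collapse = ", "))
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Construct a genotype dataset
#'
#' The central container: an `n_samples x n_markers` matrix of A2-allele
#' dosages (0 = hom A1, 1 = het, 2 = hom A2, `NA` = missing call) plus the
#' marker map and per-sample metadata (sample id and population label).
#'
#' @param genotypes integer matrix, samples in rows, markers in columns.
#' @param map a [marker_map()].
#' @param samples data.frame with columns `sample_id` and `population`.
#' @return object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, map, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!inherits(map, "marker_map")) {
    map <- marker_map(map$chrom, map$marker_id, map$pos_bp,
                      quality = map$quality, a1 = map$a1, a2 = map$a2)
  }
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "population") %in% names(samples)))
  samples <- data.frame(sample_id = as.character(samples$sample_id),
                        population = as.character(samples$population),
                        stringsAsFactors = FALSE)
  if (nrow(genotypes) != nrow(samples)) {
    stop("genotype rows (", nrow(genotypes), ") != samples (", nrow(samples), ")")
  }
  if (ncol(genotypes) != nrow(map)) {
    stop("genotype columns (", ncol(genotypes), ") != markers (", nrow(map), ")")
  }
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (any(!nzchar(samples$population)) || anyNA(samples$population)) {
    stop("population labels must be non-empty")
  }
  dimnames(genotypes) <- list(samples$sample_id, map$marker_id)
  structure(list(genotypes = genotypes, map = map, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "markers\n")
  cat("  populations:", paste(sprintf("%s (%d)",
      names(table(x$samples$population)),
      as.integer(table(x$samples$population))), collapse = ", "), "\n")
  cat("  chromosomes:", length(unique(x$map$chrom)),
      " missing rate:", signif(mean(is.na(x$genotypes)), 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset by samples and/or markers
#'
#' @param dataset a [genotype_dataset()].
#' @param samples logical/integer/character index over samples.
#' @param markers logical/integer/character index over markers.
#' @return a `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, markers = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(dataset$genotypes)) else samples
  if (is.character(si)) si <- match(si, dataset$samples$sample_id)
  mi <- if (is.null(markers)) seq_len(ncol(dataset$genotypes)) else markers
  if (is.character(mi)) mi <- match(mi, dataset$map$marker_id)
  map <- dataset$map[mi, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  genotype_dataset(dataset$genotypes[si, mi, drop = FALSE], map,
                   dataset$samples[si, , drop = FALSE])
}

#' Autosomal marker-map extent
#'
#' Total autosomal length covered by the marker map: the sum, over
#' chromosomes, of (last marker position - first marker position + 1).
#' This is the denominator L_TOTAL of the ROH-based inbreeding coefficient
#' and of the ROHet heterozygosity coefficient; it is always recomputed from
#' the marker set in force, never hard-coded.
#'
#' @param map a [marker_map()] (or a `genotype_dataset`, whose map is used).
#' @param autosomes_only drop non-autosomal chromosomes first (default TRUE).
#' @return integer scalar (double storage), total covered bp.
#' @export
genome_extent <- function(map, autosomes_only = TRUE) {
  if (inherits(map, "genotype_dataset")) map <- map$map
  if (autosomes_only) map <- map[map$chrom %in% AUTOSOMES, , drop = FALSE]
  if (!nrow(map)) stop("no autosomal markers in map")
  spans <- tapply(map$pos_bp, map$chrom, function(p) max(p) - min(p) + 1)
  sum(as.numeric(spans))
}

#' Flip dosage orientation to match a reference allele assignment
#'
#' PED/MAP text files carry no allele orientation, so a reader must adopt a
#' convention (first allele observed per marker = A2). When comparing two
#' datasets of the same markers read under different conventions, this
#' realigns dosages: wherever the recorded A2 differs from `ref_a2`, dosage
#' `g` becomes `2 - g`.
#'
#' @param dataset a [genotype_dataset()] whose map carries `a1`/`a2` columns.
#' @param ref_a2 character vector of reference A2 alleles, in marker order.
#' @return the realigned `genotype_dataset`.
#' @export
align_alleles <- function(dataset, ref_a2) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            !is.null(dataset$map$a2),
            length(ref_a2) == nrow(dataset$map))
  flip <- !is.na(ref_a2) & !is.na(dataset$map$a2) & dataset$map$a2 != ref_a2
  if (any(flip)) {
    dataset$genotypes[, flip] <- 2L - dataset$genotypes[, flip, drop = FALSE]
    tmp <- dataset$map$a1[flip]
    dataset$map$a1[flip] <- dataset$map$a2[flip]
    dataset$map$a2[flip] <- tmp
  }
  dataset
}
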