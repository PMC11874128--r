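#' Build (or read) a pipeline run configuration
#'
#' A run configuration bundles everything the end-to-end pipeline needs:
#' the PLINK input prefix, both QC tracks, run-detection parameters,
#' hotspot thresholds, an output directory and one RNG seed that governs
#' every stochastic step. It serialises loss-free to YAML.
#'
#' @param input_prefix path prefix of the input PLINK files (text
#'   `.ped`/`.map` or binary `.bed`/`.bim`/`.fam`).
#' @param out_dir output directory (created if absent).
#' @param rng_seed integer seed.
#' @param qc_strict,qc_lenient [qc_config()]s for the two tracks.
#' @param roh,rohet [roh_params()] / [rohet_params()].
#' @param roh_threshold,rohet_threshold [threshold_spec()]s for hotspot
#'   calling.
#' @param merge_gap_bp island merge gap.
#' @param annotation_path optional BED/GFF3 interval file for island
#'   annotation.
#' @param pca_k number of principal components to report.
#' @return a `run_config` list.
#' @export
run_config <- function(input_prefix, out_dir, rng_seed,
                       qc_strict = qc_config("strict"),
                       qc_lenient = qc_config("lenient"),
                       roh = roh_params(), rohet = rohet_params(),
                       roh_threshold = threshold_spec("combined", 0.005),
                       rohet_threshold = threshold_spec("top_quantile", 0.001),
                       merge_gap_bp = 5e5, annotation_path = NULL,
                       pca_k = 10) {
  structure(list(input_prefix = input_prefix, out_dir = out_dir,
                 rng_seed = as.integer(rng_seed), qc_strict = qc_strict,
                 qc_lenient = qc_lenient, roh = roh, rohet = rohet,
                 roh_threshold = roh_threshold,
                 rohet_threshold = rohet_threshold,
                 merge_gap_bp = merge_gap_bp,
                 annotation_path = annotation_path, pca_k = pca_k),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to write to / read from.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      x <- x[!vapply(x, is.null, logical(1))]
      attr(x, "class") <- NULL
    }
    x
  }
  cl <- list(config = strip(unclass(config)),
             classes = list(qc_strict = "qc_config", qc_lenient = "qc_config",
                            roh = "roh_params", rohet = "rohet_params",
                            roh_threshold = "threshold_spec",
                            rohet_threshold = "threshold_spec"))
  yaml::write_yaml(cl, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cl <- yaml::read_yaml(path)
  cfg <- cl$config
  for (nm in names(cl$classes)) {
    if (!is.null(cfg[[nm]])) class(cfg[[nm]]) <- cl$classes[[nm]]
  }
  # YAML has no NULL-vs-absent distinction for optional fields
  if (is.null(cfg$annotation_path)) cfg$annotation_path <- NULL
  class(cfg) <- "run_config"
  cfg
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on one input dataset: read genotypes,
#' QC (strict and lenient tracks), ROH and ROHet detection on the lenient
#' marker set, inbreeding coefficients (F_ROH by class on the lenient
#' extent; F_G and F_exH on the strict set) with their correlation matrix,
#' per-population incidence tracks and hotspot islands with
#' cross-population overlaps (and annotation when an interval file is
#' configured), diversity and structure summaries (Ho/He/PN, IBS distances,
#' PCA, NJ trees at sample and population level), and the Tukey comparison
#' tables of run counts. Every stage writes fixed-header TSVs under
#' `out_dir`; a JSON run manifest with input checksums, a config hash and
#' per-stage row counts is written last. A stage failure aborts with an
#' error naming the stage.
#'
#' @param config a [run_config()] or path to its YAML.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- input ----
  px <- config$input_prefix
  text_in <- file.exists(paste0(px, ".ped"))
  bin_in <- file.exists(paste0(px, ".bed"))
  if (!text_in && !bin_in) {
    stop("config error: no PLINK input at prefix '", px, "'")
  }
  inputs <- if (text_in) paste0(px, c(".ped", ".map")) else
    paste0(px, c(".bed", ".bim", ".fam"))
  dataset <- stage("read", {
    if (text_in) read_plink_text(inputs[1], inputs[2]) else
      read_plink_binary(inputs[1], inputs[2], inputs[3])
  })
  message("read: ", nrow(dataset$genotypes), " samples x ",
          ncol(dataset$genotypes), " markers")

  # ---- qc ----
  qc_l <- stage("qc_lenient", apply_qc(dataset, config$qc_lenient))
  qc_s <- stage("qc_strict", apply_qc(dataset, config$qc_strict))
  .write_tsv(qc_l$report$steps, file.path(out, "qc_lenient.tsv"))
  .write_tsv(qc_s$report$steps, file.path(out, "qc_strict.tsv"))
  ds_l <- qc_l$dataset; ds_s <- qc_s$dataset
  counts$markers_lenient <- ncol(ds_l$genotypes)
  counts$markers_strict <- ncol(ds_s$genotypes)
  counts$samples_lenient <- nrow(ds_l$genotypes)
  message("qc: lenient ", counts$markers_lenient, " markers, strict ",
          counts$markers_strict, " markers")

  # ---- runs ----
  roh <- stage("roh", detect_roh(ds_l, config$roh))
  rohet <- stage("rohet", detect_rohet(ds_l, config$rohet))
  write_runs(roh, file.path(out, "runs_roh.tsv"))
  write_runs(rohet, file.path(out, "runs_rohet.tsv"))
  counts$n_roh <- nrow(roh$runs); counts$n_rohet <- nrow(rohet$runs)
  message("runs: ", counts$n_roh, " ROH, ", counts$n_rohet, " ROHet")
  sum_roh <- summarize_runs(roh, samples = ds_l$samples, dataset = ds_l)
  sum_rohet <- summarize_runs(rohet, samples = ds_l$samples, dataset = ds_l)
  .write_tsv(sum_roh$class_summary, file.path(out, "roh_class_summary.tsv"))
  .write_tsv(sum_rohet$class_summary, file.path(out, "rohet_class_summary.tsv"))

  # ---- inbreeding ----
  inb <- stage("inbreeding", {
    extent <- genome_extent(ds_l)
    froh <- f_roh(roh, extent, samples = ds_l$samples)
    grm <- grm_vanraden(ds_s)
    fex <- f_exh(ds_s)
    hc <- het_coefficient(rohet, extent, samples = ds_l$samples)
    tab <- inbreeding_table(froh, grm, fex, hc)
    corr <- inbreeding_correlations(tab)
    list(tab = tab, corr = corr)
  })
  .write_tsv(inb$tab, file.path(out, "inbreeding.tsv"))
  .write_tsv(cbind(coefficient = rownames(inb$corr$r),
                   as.data.frame(inb$corr$r)),
             file.path(out, "inbreeding_correlations.tsv"))
  counts$samples_inbreeding <- nrow(inb$tab)

  # ---- hotspots ----
  hot <- stage("hotspots", {
    pops <- unique(ds_l$samples$population)
    tr_roh <- incidence_track(roh, ds_l)
    tr_rohet <- incidence_track(rohet, ds_l)
    isl <- list()
    for (pp in pops) {
      isl[[paste0("roh_", pp)]] <-
        call_islands(tr_roh[tr_roh$population == pp, ],
                     config$roh_threshold, config$merge_gap_bp)
      isl[[paste0("rohet_", pp)]] <-
        call_islands(tr_rohet[tr_rohet$population == pp, ],
                     config$rohet_threshold, config$merge_gap_bp)
    }
    islands <- do.call(rbind, c(isl, list(make.row.names = FALSE)))
    shared <- overlap_islands(islands)
    list(tracks = rbind(tr_roh, tr_rohet), islands = islands,
         shared = shared)
  })
  .write_tsv(hot$tracks, file.path(out, "incidence_tracks.tsv"))
  .write_tsv(hot$islands, file.path(out, "islands.tsv"))
  .write_tsv(hot$shared, file.path(out, "islands_shared.tsv"))
  counts$n_islands <- nrow(hot$islands)
  counts$n_shared_regions <- nrow(hot$shared)
  message("hotspots: ", counts$n_islands, " islands, ",
          counts$n_shared_regions, " shared regions")
  if (!is.null(config$annotation_path)) {
    ann <- stage("annotation",
                 annotate_islands(hot$islands, config$annotation_path))
    .write_tsv(ann, file.path(out, "islands_annotated.tsv"))
    counts$n_annotations <- nrow(ann)
  }

  # ---- structure ----
  str_res <- stage("structure", {
    div <- diversity_summary(ds_s)
    D <- ibs_distance(ds_s)
    pca <- pca_genotypes(ds_s, k = min(config$pca_k,
                                       nrow(ds_s$genotypes) - 1))
    pops <- ds_s$samples$population
    tree_pop <- if (length(unique(pops)) >= 3)
      nj_tree(population_distance(D, pops)) else NULL
    tree_sample <- if (nrow(D) >= 3) nj_tree(D) else NULL
    list(div = div, D = D, pca = pca, tree_pop = tree_pop,
         tree_sample = tree_sample)
  })
  .write_tsv(str_res$div, file.path(out, "diversity.tsv"))
  .write_tsv(cbind(sample_id = rownames(str_res$D),
                   as.data.frame(str_res$D)),
             file.path(out, "ibs_distances.tsv"))
  .write_tsv(cbind(sample_id = rownames(str_res$pca$coordinates),
                   population = ds_s$samples$population,
                   as.data.frame(str_res$pca$coordinates)),
             file.path(out, "pca_coordinates.tsv"))
  .write_tsv(data.frame(component = seq_along(str_res$pca$variance_pct),
                        variance_pct = str_res$pca$variance_pct),
             file.path(out, "pca_variance.tsv"))
  if (!is.null(str_res$tree_pop)) {
    write_newick(str_res$tree_pop, file.path(out, "tree_populations.nwk"))
  }
  if (!is.null(str_res$tree_sample)) {
    write_newick(str_res$tree_sample, file.path(out, "tree_samples.nwk"))
  }

  # ---- breed comparisons ----
  cmp <- stage("compare", {
    if (length(unique(ds_l$samples$population)) >= 2 &&
        all(table(ds_l$samples$population) >= 2)) {
      list(roh = compare_run_counts(roh, ds_l$samples),
           rohet = compare_run_counts(rohet, ds_l$samples))
    } else NULL
  })
  if (!is.null(cmp)) {
    .write_tsv(cmp$roh, file.path(out, "compare_roh_counts.tsv"))
    .write_tsv(cmp$rohet, file.path(out, "compare_rohet_counts.tsv"))
  }

  # ---- manifest ----
  cfg_file <- file.path(out, "run_config.yaml")
  write_run_config(config, cfg_file)
  manifest <- list(
    tool = "runscape",
    version = as.character(utils::packageVersion("runscape")),
    config_hash = unname(tools::md5sum(cfg_file)),
    inputs = as.list(stats::setNames(as.character(tools::md5sum(inputs)),
                                     basename(inputs))),
    counts = counts,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
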