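#' Describe the demographic history of one simulated population
#'
#' Three stylised histories cover the structures the downstream analyses
#' need ground truth for:
#' * `"founder_pairs"` - each sample is the child of its own pair of
#'   unrelated founders: pedigree inbreeding F = 0 and no background
#'   relatedness (the non-inbred control).
#' * `"fullsib_loops"` - each sample is the child of a full-sib mating
#'   (own founder quartet): F = 0.25, producing the long autozygous
#'   segments of recent inbreeding.
#' * `"random_mating"` - `n_founders` founders followed by
#'   `n_generations` of random mating at constant size; drift builds the
#'   background relatedness that yields short segments.
#'
#' @param label population label.
#' @param n_samples individuals in the final (sampled) generation.
#' @param history one of the histories above.
#' @param n_founders founder count for `"random_mating"`.
#' @param n_generations generations of random mating.
#' @return a `population_design` list.
#' @export
population_design <- function(label, n_samples,
                              history = c("founder_pairs", "fullsib_loops",
                                          "random_mating"),
                              n_founders = 20, n_generations = 5) {
  history <- match.arg(history)
  stopifnot(nzchar(label), n_samples >= 1, n_founders >= 2, n_generations >= 1)
  structure(list(label = label, n_samples = n_samples, history = history,
                 n_founders = n_founders, n_generations = n_generations),
            class = "population_design")
}

#' Build a pedigree from population designs
#'
#' @param designs a `population_design` or list of them.
#' @param seed optional seed for the random-mating history (mate choice).
#' @return a `pedigree` data.frame: `id`, `sire`, `dam` (NA for founders),
#'   `generation`, `population`, `is_sample`.
#' @export
build_pedigree <- function(designs, seed = NULL) {
  if (inherits(designs, "population_design")) designs <- list(designs)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  add <- function(id, sire, dam, gen, pop, is_sample = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, generation = gen,
      population = pop, is_sample = is_sample, stringsAsFactors = FALSE)
  }
  for (d in designs) {
    pl <- d$label
    if (d$history == "founder_pairs") {
      for (i in seq_len(d$n_samples)) {
        f1 <- sprintf("%s_F%da", pl, i); f2 <- sprintf("%s_F%db", pl, i)
        add(f1, NA, NA, 0L, pl); add(f2, NA, NA, 0L, pl)
        add(sprintf("%s_S%d", pl, i), f1, f2, 1L, pl, TRUE)
      }
    } else if (d$history == "fullsib_loops") {
      for (i in seq_len(d$n_samples)) {
        f1 <- sprintf("%s_F%da", pl, i); f2 <- sprintf("%s_F%db", pl, i)
        s1 <- sprintf("%s_B%da", pl, i); s2 <- sprintf("%s_B%db", pl, i)
        add(f1, NA, NA, 0L, pl); add(f2, NA, NA, 0L, pl)
        add(s1, f1, f2, 1L, pl); add(s2, f1, f2, 1L, pl)
        add(sprintf("%s_S%d", pl, i), s1, s2, 2L, pl, TRUE)
      }
    } else {
      prev <- sprintf("%s_G0_%d", pl, seq_len(d$n_founders))
      for (id in prev) add(id, NA, NA, 0L, pl)
      for (g in seq_len(d$n_generations)) {
        size <- if (g == d$n_generations) d$n_samples else
          max(d$n_founders, d$n_samples)
        cur <- sprintf("%s_G%d_%d", pl, g, seq_len(size))
        for (i in seq_len(size)) {
          par <- sample(prev, 2)
          add(cur[i], par[1], par[2], g, pl, g == d$n_generations)
        }
        prev <- cur
      }
    }
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  validate_pedigree(ped)
}

#' Validate (and class) a pedigree data.frame
#'
#' Checks acyclicity (parents precede offspring in topological order),
#' founders having no parents, and id uniqueness.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`, and optionally
#'   `generation`, `population`, `is_sample`.
#' @return the `pedigree` object.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate pedigree ids")
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  for (col in c("sire", "dam")) {
    known <- is.na(ped[[col]]) | ped[[col]] %in% ped$id
    if (!all(known)) stop("unknown ", col, " id: ", ped[[col]][!known][1])
  }
  si <- idx[ped$sire]; di <- idx[ped$dam]
  if (any(!is.na(si) & si >= idx) || any(!is.na(di) & di >= idx)) {
    stop("parents must precede offspring in pedigree order")
  }
  if (any(xor(is.na(ped$sire), is.na(ped$dam)))) {
    stop("individuals must have both parents or none")
  }
  if (is.null(ped$generation)) {
    gen <- integer(nrow(ped))
    for (i in idx) {
      gen[i] <- if (is.na(si[i])) 0L else max(gen[si[i]], gen[di[i]]) + 1L
    }
    ped$generation <- gen
  }
  if (is.null(ped$population)) ped$population <- "P1"
  if (is.null(ped$is_sample)) ped$is_sample <- ped$generation == max(ped$generation)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Pedigree inbreeding coefficients (tabular kinship method)
#'
#' Computes per-individual F as the kinship of the parents, by the standard
#' recursive (tabular) coancestry method.
#'
#' @param ped a `pedigree`.
#' @return named numeric vector of F, one per individual.
#' @export
pedigree_inbreeding <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  K <- matrix(0, n, n)
  f <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      K[i, i] <- 0.5
    } else {
      f[i] <- K[si[i], di[i]]
      K[i, i] <- 0.5 * (1 + f[i])
      prev <- seq_len(i - 1L)
      kij <- 0.5 * (K[si[i], prev] + K[di[i], prev])
      K[i, prev] <- kij
      K[prev, i] <- kij
    }
  }
  stats::setNames(f, ped$id)
}

#' Simulation configuration for the gene-drop generator
#'
#' Defaults model a medium-density autosomal SNP panel at desk scale:
#' 5 chromosomes of 50 Mb with 1,000 evenly spaced markers each (50 kb
#' spacing, comparable to a 60K panel on a 2.5 Gb genome), founder allele
#' frequencies from a Beta(0.5, 0.5) truncated to \[0.05, 0.95\], a uniform
#' 1 cM/Mb genetic map with Haldane (no-interference, Poisson) crossovers,
#' and a 0.5% missing-call rate.
#'
#' @param n_chromosomes,chromosome_length_bp,markers_per_chromosome panel
#'   geometry.
#' @param founder_beta shape parameters of the founder frequency Beta.
#' @param founder_freq_range truncation interval for founder frequencies.
#' @param cm_per_mb genetic-map scale.
#' @param missing_rate per-call missing probability, applied last.
#' @param marker_spacing `"clustered"` (default) draws lognormal
#'   inter-marker gaps (dispersion `spacing_sdlog`), emulating the strongly right-skewed
#'   spacing of real arrays - locally dense stretches are what allow e.g.
#'   a 50-SNP run to span well under 50 average spacings; `"uniform"`
#'   places markers at sorted uniform positions (exponential-like gaps);
#'   `"even"` uses a regular grid.
#' @param spacing_sdlog log-scale SD of the clustered gap distribution
#'   (default 1.0, the order of dispersion seen on livestock arrays).
#' @param rng_seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 5, chromosome_length_bp = 5e7,
                       markers_per_chromosome = 1000,
                       founder_beta = c(0.5, 0.5),
                       founder_freq_range = c(0.05, 0.95),
                       cm_per_mb = 1, missing_rate = 0.005,
                       marker_spacing = c("clustered", "uniform", "even"),
                       spacing_sdlog = 1.0, rng_seed) {
  marker_spacing <- match.arg(marker_spacing)
  stopifnot(n_chromosomes >= 1, chromosome_length_bp >= 2,
            markers_per_chromosome >= 2,
            missing_rate >= 0, missing_rate <= 1,
            length(founder_beta) == 2, all(founder_beta > 0),
            founder_freq_range[1] >= 0, founder_freq_range[2] <= 1,
            founder_freq_range[1] < founder_freq_range[2])
  if (missing(rng_seed)) stop("rng_seed is mandatory for reproducibility")
  structure(list(n_chromosomes = n_chromosomes,
                 chromosome_length_bp = chromosome_length_bp,
                 markers_per_chromosome = markers_per_chromosome,
                 founder_beta = founder_beta,
                 founder_freq_range = founder_freq_range,
                 cm_per_mb = cm_per_mb, missing_rate = missing_rate,
                 marker_spacing = marker_spacing,
                 spacing_sdlog = spacing_sdlog,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# clip ancestry segments (3-col matrix start,end,fid) to [lo, hi]
.clip_segments <- function(seg, lo, hi) {
  keep <- seg[, 2] >= lo & seg[, 1] <= hi
  s <- seg[keep, , drop = FALSE]
  if (nrow(s)) {
    s[, 1] <- pmax(s[, 1], lo)
    s[, 2] <- pmin(s[, 2], hi)
  }
  s
}

.merge_segments <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  keep <- logical(nrow(seg))
  keep[1] <- TRUE
  j <- 1L
  for (i in 2:nrow(seg)) {
    if (seg[i, 3] == seg[j, 3] && seg[i, 1] <= seg[j, 2] + 1) {
      seg[j, 2] <- max(seg[j, 2], seg[i, 2])
    } else {
      j <- i; keep[i] <- TRUE
    }
  }
  seg[keep, , drop = FALSE]
}

#' Gene-drop simulation over a pedigree
#'
#' Founder haplotypes are drawn marker-wise from the configured frequency
#' distribution; descendants inherit recombinant haplotypes (Poisson
#' crossover counts per the Haldane model, uniform crossover positions, a
#' uniform cM/Mb map). Each founder haplotype carries a unique label whose
#' transmission is tracked in base-pair segments, so autozygosity (both
#' haplotypes tracing to the same founder haplotype) is known exactly.
#' Genotypes are A2-allele dosages; missingness is applied last.
#'
#' @param pedigree a `pedigree` (see [build_pedigree()]).
#' @param config a [sim_config()].
#' @return list with `dataset` (a [genotype_dataset()] of the sampled
#'   individuals) and `truth` (a `sim_truth`: per-sample pedigree F and
#'   realized IBD genome fraction, true IBD segments >= 10 kb, and an empty
#'   island table filled by [plant_islands()]).
#' @export
gene_drop <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  ped <- validate_pedigree(pedigree)
  set.seed(config$rng_seed)
  nc <- config$n_chromosomes
  L <- config$chromosome_length_bp
  mpc <- config$markers_per_chromosome
  if (nc * mpc < 1) stop("zero markers configured")

  pos_by_chr <- lapply(seq_len(nc), function(cc) {
    pos <- switch(config$marker_spacing,
      even = round(seq_len(mpc) * (L / (mpc + 1))),
      uniform = sort(sample.int(L - 1, mpc)),
      clustered = {
        gaps <- stats::rlnorm(mpc + 1, meanlog = 0, sdlog = config$spacing_sdlog)
        round(cumsum(gaps)[seq_len(mpc)] / sum(gaps) * (L - 1))
      })
    # enforce strictly increasing integer positions >= 1
    pos <- pmax(pos, seq_len(mpc))
    while (any(d <- diff(pos) <= 0)) pos[which(d) + 1] <- pos[which(d)] + 1
    pos
  })
  map <- marker_map(chrom = rep(as.character(seq_len(nc)), each = mpc),
                    marker_id = sprintf("snp_%d_%d",
                                        rep(seq_len(nc), each = mpc),
                                        rep(seq_len(mpc), nc)),
                    pos_bp = unlist(pos_by_chr),
                    a1 = rep("A", nc * mpc), a2 = rep("G", nc * mpc))
  m_total <- nc * mpc
  col_of <- split(seq_len(m_total), rep(seq_len(nc), each = mpc))

  ab <- config$founder_beta; fr <- config$founder_freq_range
  u <- stats::runif(m_total, stats::pbeta(fr[1], ab[1], ab[2]),
                    stats::pbeta(fr[2], ab[1], ab[2]))
  p <- stats::qbeta(u, ab[1], ab[2])

  n <- nrow(ped)
  gametes <- vector("list", n)   # each: list(h1, h2); h = list(al, anc)
  fid_counter <- 0L
  new_founder_hap <- function() {
    fid_counter <<- fid_counter + 1L
    list(al = stats::rbinom(m_total, 1L, p),
         anc = lapply(seq_len(nc), function(cc)
           matrix(c(1, L, fid_counter), 1, 3)))
  }
  meiosis <- function(parent_gam) {
    al <- integer(m_total)
    anc <- vector("list", nc)
    cm_chr <- (L / 1e6) * config$cm_per_mb
    for (cc in seq_len(nc)) {
      nx <- stats::rpois(1, cm_chr / 100)
      bps <- sort(stats::runif(nx, 1, L))
      phase <- sample(1:2, 1)
      idx <- col_of[[cc]]
      src <- ifelse(findInterval(map$pos_bp[idx], bps) %% 2 == 0,
                    phase, 3L - phase)
      al[idx] <- ifelse(src == 1, parent_gam$h1$al[idx], parent_gam$h2$al[idx])
      bounds <- c(1, bps, L + 1)
      segs <- list()
      for (k in seq_len(length(bounds) - 1)) {
        h <- if ((k - 1) %% 2 == 0) phase else 3L - phase
        src_anc <- if (h == 1) parent_gam$h1$anc[[cc]] else parent_gam$h2$anc[[cc]]
        piece <- .clip_segments(src_anc, ceiling(bounds[k]), floor(bounds[k + 1] - 1e-9))
        if (nrow(piece)) segs[[length(segs) + 1L]] <- piece
      }
      anc[[cc]] <- .merge_segments(do.call(rbind, segs))
    }
    list(al = al, anc = anc)
  }

  idx <- seq_len(n); names(idx) <- ped$id
  for (i in seq_len(n)) {
    if (is.na(ped$sire[i])) {
      gametes[[i]] <- list(h1 = new_founder_hap(), h2 = new_founder_hap())
    } else {
      gametes[[i]] <- list(h1 = meiosis(gametes[[idx[ped$sire[i]]]]),
                           h2 = meiosis(gametes[[idx[ped$dam[i]]]]))
    }
  }

  samp_i <- which(ped$is_sample)
  G <- t(vapply(samp_i, function(i)
    gametes[[i]]$h1$al + gametes[[i]]$h2$al, integer(m_total)))
  f_ped <- pedigree_inbreeding(ped)[samp_i]

  # true autozygous segments: equal founder-haplotype label on both gametes
  seg_rows <- list()
  f_ibd <- numeric(length(samp_i))
  for (k in seq_along(samp_i)) {
    i <- samp_i[k]
    tot <- 0
    for (cc in seq_len(nc)) {
      s1 <- gametes[[i]]$h1$anc[[cc]]
      s2 <- gametes[[i]]$h2$anc[[cc]]
      cuts <- sort(unique(c(s1[, 1], s1[, 2] + 1, s2[, 1], s2[, 2] + 1)))
      lo <- cuts[-length(cuts)]; hi <- cuts[-1] - 1
      f1 <- s1[findInterval(lo, s1[, 1]), 3]
      f2 <- s2[findInterval(lo, s2[, 1]), 3]
      auto <- f1 == f2
      if (any(auto)) {
        seg <- .merge_segments(cbind(lo[auto], hi[auto], 1)[order(lo[auto]), ,
                                                            drop = FALSE])
        seg <- seg[seg[, 2] - seg[, 1] + 1 >= 1e4, , drop = FALSE]
        if (nrow(seg)) {
          tot <- tot + sum(seg[, 2] - seg[, 1] + 1)
          seg_rows[[length(seg_rows) + 1L]] <- data.frame(
            sample_id = ped$id[i], chrom = as.character(cc),
            start_bp = seg[, 1], end_bp = seg[, 2])
        }
      }
    }
    f_ibd[k] <- tot / (nc * L)
  }

  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(G)) < config$missing_rate, nrow(G))
    G[drop] <- NA_integer_
  }
  dataset <- genotype_dataset(G, map,
                              data.frame(sample_id = ped$id[samp_i],
                                         population = ped$population[samp_i]))
  truth <- structure(list(
    samples = data.frame(sample_id = ped$id[samp_i],
                         population = ped$population[samp_i],
                         f_ped = as.numeric(f_ped), f_ibd = f_ibd),
    ibd_segments = if (length(seg_rows)) do.call(rbind, seg_rows) else
      data.frame(sample_id = character(0), chrom = character(0),
                 start_bp = numeric(0), end_bp = numeric(0)),
    islands = data.frame(population = character(0), chrom = character(0),
                         start_bp = numeric(0), end_bp = numeric(0),
                         mode = character(0), target_fraction = numeric(0),
                         realized_fraction = numeric(0)),
    founder_freq = p), class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Specify an island to plant
#'
#' @param chrom chromosome label.
#' @param start_bp,end_bp island interval (1-based, inclusive).
#' @param mode `"roh"` (shared homozygous haplotype) or `"rohet"` (forced
#'   heterozygosity).
#' @param target_carrier_fraction fraction of the population to overwrite,
#'   in (0, 1].
#' @param population population label the island applies to.
#' @return an `island_spec` list.
#' @export
island_spec <- function(chrom, start_bp, end_bp, mode = c("roh", "rohet"),
                        target_carrier_fraction, population) {
  mode <- match.arg(mode)
  stopifnot(start_bp >= 1, end_bp > start_bp,
            target_carrier_fraction > 0, target_carrier_fraction <= 1)
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp, mode = mode,
                 target_carrier_fraction = target_carrier_fraction,
                 population = population), class = "island_spec")
}

#' Plant low-diversity (ROH) or balanced (ROHet) islands into a dataset
#'
#' For `round(fraction * n)` carriers (chosen by the seeded RNG) the
#' genotypes inside the interval are overwritten: `roh` mode writes a
#' shared homozygous haplotype (the same across carriers, drawn once from
#' the founder frequencies), `rohet` mode writes heterozygous calls at
#' every interval marker. Realized carrier fractions are recorded in the
#' truth object.
#'
#' @param dataset a [genotype_dataset()].
#' @param truth the matching `sim_truth` (or NULL).
#' @param island_specs list of [island_spec()]s.
#' @param seed RNG seed for carrier choice and the shared haplotype.
#' @return list(`dataset`, `truth`) with islands applied and recorded.
#' @export
plant_islands <- function(dataset, truth, island_specs, seed) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (inherits(island_specs, "island_spec")) island_specs <- list(island_specs)
  set.seed(seed)
  map <- dataset$map
  for (sp in island_specs) {
    mi <- which(map$chrom == sp$chrom & map$pos_bp >= sp$start_bp &
                map$pos_bp <= sp$end_bp)
    if (!length(mi)) stop("island contains no markers: ", sp$chrom, ":",
                          sp$start_bp, "-", sp$end_bp)
    pop_i <- which(dataset$samples$population == sp$population)
    if (!length(pop_i)) stop("no samples in population ", sp$population)
    n_car <- round(sp$target_carrier_fraction * length(pop_i))
    carriers <- sample(pop_i, n_car)
    if (sp$mode == "roh") {
      fr <- allele_frequencies(subset_dataset(dataset, markers = mi))
      pj <- ifelse(is.na(fr$p), 0.5, fr$p)
      hap <- stats::rbinom(length(mi), 1L, pj)
      dataset$genotypes[carriers, mi] <-
        matrix(2L * hap, length(carriers), length(mi), byrow = TRUE)
    } else {
      dataset$genotypes[carriers, mi] <- 1L
    }
    if (!is.null(truth)) {
      truth$islands <- rbind(truth$islands, data.frame(
        population = sp$population, chrom = sp$chrom,
        start_bp = sp$start_bp, end_bp = sp$end_bp, mode = sp$mode,
        target_fraction = sp$target_carrier_fraction,
        realized_fraction = n_car / length(pop_i)))
    }
  }
  list(dataset = dataset, truth = truth)
}

#' Write simulation truth tables as TSV
#'
#' @param truth a `sim_truth`.
#' @param prefix output prefix; writes `<prefix>_truth_samples.tsv`,
#'   `<prefix>_truth_ibd.tsv`, `<prefix>_truth_islands.tsv`.
#' @export
write_sim_truth <- function(truth, prefix) {
  paths <- c(samples = paste0(prefix, "_truth_samples.tsv"),
             ibd = paste0(prefix, "_truth_ibd.tsv"),
             islands = paste0(prefix, "_truth_islands.tsv"))
  utils::write.table(truth$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$ibd_segments, paths["ibd"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$islands, paths["islands"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
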