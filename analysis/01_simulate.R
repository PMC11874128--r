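#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-breed cohort.
#
# Five goat-like populations with contrasting demographic histories stand in
# for a real SNP-array cohort ("data available upon request" situations):
#   ALPINE_A / ALPINE_B  - moderate-size herds, random mating (moderate F)
#   MED_A                - random mating with a recent full-sib cohort
#   MED_B                - random mating, larger founder pool (low F)
#   ISLAND               - small drifted population (highest background F)
# Planted islands give the hotspot stages known answers: one ROH island
# shared by three populations, one population-private ROH island, and one
# shared ROHet island. A synthetic gene annotation covers the genome so the
# annotation stage has intervals to hit.

suppressMessages(library(runscape))

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260915

designs <- list(
  population_design("ALPINE_A", 30, "random_mating", n_founders = 24,
                    n_generations = 8),
  population_design("ALPINE_B", 30, "random_mating", n_founders = 20,
                    n_generations = 10),
  population_design("MED_A", 30, "fullsib_loops"),
  population_design("MED_B", 30, "random_mating", n_founders = 40,
                    n_generations = 6),
  population_design("ISLAND", 30, "random_mating", n_founders = 10,
                    n_generations = 20))

ped <- build_pedigree(designs, seed = seed)
cfg <- sim_config(n_chromosomes = 3, chromosome_length_bp = 5e7,
                  markers_per_chromosome = 1200, rng_seed = seed + 1)
sim <- gene_drop(ped, cfg)

islands <- c(
  lapply(c("ALPINE_A", "ALPINE_B", "MED_A"), function(pp)
    island_spec("1", 12e6, 17e6, "roh", 0.7, pp)),     # shared ROH island
  list(island_spec("2", 30e6, 35e6, "roh", 0.65, "ISLAND"),  # private island
       island_spec("3", 8e6, 11e6, "rohet", 0.6, "ALPINE_A"),
       island_spec("3", 8e6, 11e6, "rohet", 0.6, "MED_B")))  # shared ROHet
planted <- plant_islands(sim$dataset, sim$truth, islands, seed = seed + 2)

write_plink_text(planted$dataset, file.path(out_dir, "cohort"))
write_plink_binary(planted$dataset, file.path(out_dir, "cohort"))
write_sim_truth(planted$truth, file.path(out_dir, "cohort"))

# synthetic gene annotation: 120 evenly scattered "genes" of 50-400 kb
set.seed(seed + 3)
genes <- do.call(rbind, lapply(1:3, function(chr) {
  starts <- sort(sample.int(5e7 - 5e5, 40))
  data.frame(chrom = chr, start0 = starts,
             end0 = starts + sample(5e4:4e5, 40, replace = TRUE),
             name = sprintf("GENE_%d_%02d", chr, 1:40))
}))
write.table(genes, file.path(out_dir, "genes_synthetic.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

tm <- planted$truth$samples
message(sprintf("cohort: %d samples x %d markers, %d populations",
                nrow(planted$dataset$genotypes),
                ncol(planted$dataset$genotypes),
                length(unique(tm$population))))
for (pp in unique(tm$population)) {
  message(sprintf("  %-9s mean pedigree F = %.3f, mean true IBD = %.3f",
                  pp, mean(tm$f_ped[tm$population == pp]),
                  mean(tm$f_ibd[tm$population == pp])))
}
message("wrote PLINK text+binary, truth tables and synthetic annotation to ",
        out_dir)
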