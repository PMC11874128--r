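#!/usr/bin/env Rscript
# Stage 5: diversity and population structure.
#
# Per-population observed/expected heterozygosity and polymorphism on the
# strict marker set; sample-level identity-by-state distances; principal
# components of the centered dosage matrix; neighbor-joining trees at the
# sample and population level, exported as Newick.

suppressMessages(library(runscape))

out_dir <- "results"
dataset <- read_plink_binary("results/sim/cohort.bed", "results/sim/cohort.bim",
                             "results/sim/cohort.fam")
qc_s <- apply_qc(dataset, qc_config("strict"))
ds <- qc_s$dataset

div <- diversity_summary(ds)
write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("diversity per population:")
print(div, digits = 3)

D <- ibs_distance(ds)
write.table(cbind(sample_id = rownames(D), as.data.frame(D)),
            file.path(out_dir, "ibs_distances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pca <- pca_genotypes(ds, k = 10)
write.table(cbind(sample_id = rownames(pca$coordinates),
                  population = ds$samples$population,
                  as.data.frame(pca$coordinates)),
            file.path(out_dir, "pca_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(component = seq_along(pca$variance_pct),
                       variance_pct = pca$variance_pct),
            file.path(out_dir, "pca_variance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("PCA: PC1 %.2f%%, PC2 %.2f%% of variance",
                pca$variance_pct[1], pca$variance_pct[2]))

write_newick(nj_tree(D), file.path(out_dir, "tree_samples.nwk"))
PD <- population_distance(D, ds$samples$population)
write_newick(nj_tree(PD), file.path(out_dir, "tree_populations.nwk"))
message("population NJ tree: ",
        paste(readLines(file.path(out_dir, "tree_populations.nwk")),
              collapse = ""))
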