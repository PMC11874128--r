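#!/usr/bin/env Rscript
# Stage 6: population comparisons.
#
# One-way ANOVA with Tukey HSD letters on per-sample run counts in each
# length class (populations sharing a letter do not differ at alpha = 0.05),
# and Pearson tests between per-sample ROH and ROHet burden per population.

suppressMessages(library(runscape))

out_dir <- "results"
dataset <- read_plink_binary("results/sim/cohort.bed", "results/sim/cohort.bim",
                             "results/sim/cohort.fam")
qc_l <- apply_qc(dataset, qc_config("lenient"))
roh <- detect_roh(qc_l$dataset)
rohet <- detect_rohet(qc_l$dataset)
samples <- qc_l$dataset$samples

tab_roh <- compare_run_counts(roh, samples)
tab_rohet <- compare_run_counts(rohet, samples)
write.table(tab_roh, file.path(out_dir, "compare_roh_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tab_rohet, file.path(out_dir, "compare_rohet_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("ROH counts per class with Tukey letters:")
print(tab_roh, digits = 3, row.names = FALSE)

# per-population Pearson correlation between ROH and ROHet burden
sum_roh <- summarize_runs(roh, samples = samples)$per_sample
sum_rohet <- summarize_runs(rohet, samples = samples)$per_sample
stopifnot(identical(sum_roh$sample_id, sum_rohet$sample_id))
rows <- lapply(unique(samples$population), function(pp) {
  i <- sum_roh$population == pp
  x <- sum_roh$sum_length_bp[i]; y <- sum_rohet$sum_length_bp[i]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    data.frame(population = pp, r = NA_real_, p_value = NA_real_,
               n = sum(i))
  } else {
    pt <- pearson_test(x, y)
    data.frame(population = pp, r = pt$r, p_value = pt$p_value, n = pt$n)
  }
})
corr_tab <- do.call(rbind, rows)
write.table(corr_tab, file.path(out_dir, "roh_vs_rohet_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("ROH-vs-ROHet burden correlation per population:")
print(corr_tab, digits = 3, row.names = FALSE)
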