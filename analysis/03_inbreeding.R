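#!/usr/bin/env Rscript
# Stage 3: genomic inbreeding coefficients.
#
# Three estimators per sample: F_ROH (summed ROH length over the autosomal
# map extent, total and in the four length classes) on the lenient marker
# set; F_G = G_ii - 1 from the VanRaden genomic relationship matrix and
# F_exH from the excess of observed over expected homozygosity, both on the
# strict set; plus the ROHet-length heterozygosity coefficient. The Pearson
# matrix across estimators shows the usual pattern: long-segment classes
# carry the correlation with total autozygosity.

suppressMessages(library(runscape))

out_dir <- "results"
dataset <- read_plink_binary("results/sim/cohort.bed", "results/sim/cohort.bim",
                             "results/sim/cohort.fam")
qc_l <- apply_qc(dataset, qc_config("lenient"))
qc_s <- apply_qc(dataset, qc_config("strict"))
roh <- detect_roh(qc_l$dataset)
rohet <- detect_rohet(qc_l$dataset)

extent <- genome_extent(qc_l$dataset)
message(sprintf("autosomal extent covered by markers: %.0f bp", extent))

froh <- f_roh(roh, extent, samples = qc_l$dataset$samples)
grm <- grm_vanraden(qc_s$dataset)
fex <- f_exh(qc_s$dataset)
hc <- het_coefficient(rohet, extent, samples = qc_l$dataset$samples)
tab <- inbreeding_table(froh, grm, fex, hc)
write.table(tab, file.path(out_dir, "inbreeding.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("mean F_ROH / F_G / F_exH per population:")
agg <- aggregate(tab[, c("f_roh_total", "f_g", "f_exh")],
                 by = list(population = tab$population), FUN = mean)
print(agg, digits = 3)

cc <- inbreeding_correlations(tab)
write.table(cbind(coefficient = rownames(cc$r), as.data.frame(cc$r)),
            file.path(out_dir, "inbreeding_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("corr(F_ROH total, >8 Mb class) = %.3f vs (1-2 Mb) = %.3f",
                cc$r["f_roh_total", "f_roh_8_Mb"],
                cc$r["f_roh_total", "f_roh_1_2_Mb"]))
message(sprintf("corr(F_ROH, F_G) = %.3f, corr(F_ROH, F_exH) = %.3f",
                cc$r["f_roh_total", "f_g"], cc$r["f_roh_total", "f_exh"]))
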