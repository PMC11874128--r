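#!/usr/bin/env Rscript
# Stage 2: quality control and run detection.
#
# Two QC tracks mirror standard SNP-array practice: a strict track (call
# rates, MAF >= 0.05, HWE exact p > 1e-5) for relationship and structure
# analyses, and a lenient track (call rates only) for run detection, where
# monomorphic and rare markers are informative. ROH are called with the
# sliding-window method (50-SNP windows, >= 50 SNPs, >= 1 Mb, <= 500 kb
# gaps, >= 1 SNP/100 kb, <= 1 heterozygote); ROHet with the consecutive
# method (>= 15 SNPs, >= 500 kb, <= 2 missing, <= 3 homozygotes).

suppressMessages(library(runscape))

out_dir <- "results"
dataset <- read_plink_binary("results/sim/cohort.bed", "results/sim/cohort.bim",
                             "results/sim/cohort.fam")

qc_l <- apply_qc(dataset, qc_config("lenient"))
qc_s <- apply_qc(dataset, qc_config("strict"))
write_qc_report(qc_l$report, file.path(out_dir, "qc_lenient.tsv"))
write_qc_report(qc_s$report, file.path(out_dir, "qc_strict.tsv"))
message(sprintf("QC: %d markers lenient, %d markers strict (of %d)",
                ncol(qc_l$dataset$genotypes), ncol(qc_s$dataset$genotypes),
                ncol(dataset$genotypes)))

roh <- detect_roh(qc_l$dataset)
rohet <- detect_rohet(qc_l$dataset)
write_runs(roh, file.path(out_dir, "runs_roh.tsv"),
           bed_path = file.path(out_dir, "runs_roh.bed"))
write_runs(rohet, file.path(out_dir, "runs_rohet.tsv"))

for (rs in list(roh, rohet)) {
  sm <- summarize_runs(rs, samples = qc_l$dataset$samples,
                       dataset = qc_l$dataset)
  base <- tolower(rs$kind)
  write.table(sm$class_summary,
              file.path(out_dir, paste0(base, "_class_summary.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sm$per_sample,
              file.path(out_dir, paste0(base, "_per_sample.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sm$chromosome_summary,
              file.path(out_dir, paste0(base, "_per_chromosome.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d runs; per-population counts:", rs$kind,
                  nrow(rs$runs)))
  print(table(rs$runs$population, rs$runs$length_class))
}
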