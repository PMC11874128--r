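Package: runscape
Title: Runs of Homozygosity and Heterozygosity in SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of autozygosity and heterozygosity
    landscapes from SNP-array genotypes of structured (multi-breed)
    populations. Reads and writes PLINK text and binary genotype files,
    applies two-track marker and sample quality control, calls runs of
    homozygosity (ROH) with a sliding-window method and runs of
    heterozygosity (ROHet) with a consecutive-marker method, computes
    three genomic inbreeding coefficients (F_ROH in length classes, the
    VanRaden genomic-relationship diagonal F_G, and excess-homozygosity
    F_exH), detects ROH/ROHet hotspot islands under absolute and
    top-quantile incidence thresholds with cross-population overlaps and
    interval annotation, and summarises diversity and structure (observed
    and expected heterozygosity, identity-by-state distances, principal
    components, neighbor-joining trees). A pedigree gene-drop simulator
    with recombination and founder-allele tracking provides genotype
    datasets with known pedigree inbreeding, true IBD segments and
    planted islands for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
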