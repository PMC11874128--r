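---
title: "Autozygosity and heterozygosity landscapes from SNP-array genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity and heterozygosity landscapes from SNP-array genotypes}
  %\VignetteEncoding{UTF-8}
---

## The problem

Runs of homozygosity (ROH) are uninterrupted stretches of homozygous
genotypes. In livestock they are the workhorse for quantifying genomic
inbreeding: long runs arise from recent inbreeding (few meioses have had the
chance to break the autozygous chromosome), short runs from ancient
relatedness. Their mirror image, runs of heterozygosity (ROHet), marks
regions where diversity is maintained, e.g. under balancing selection.
Regions where a large fraction of a population carries a run ("islands" or
hotspots) are candidate selection signatures.

`runscape` implements this analysis stack for multi-population SNP-array
cohorts: PLINK-format I/O and two-track QC, window-based ROH and
consecutive-marker ROHet calling with length classes, three genomic
inbreeding coefficients, incidence-based hotspot islands with
cross-population overlaps and interval annotation, diversity and structure
summaries, and the ANOVA/Tukey comparison layer. Because array cohorts of
this kind are typically not publicly deposited, the package carries a
pedigree gene-drop simulator that produces genotypes with *known*
autozygosity (pedigree F, exact IBD segments, planted islands); every claim
the test suite makes about the stack is made against that ground truth.

## Data model and QC

Genotypes are held as an `n x m` integer matrix of A2-allele dosages (0, 1,
2, `NA` for missing) with a marker map (chromosome, id, 1-based bp,
optional call-quality score) and a sample sheet (id, population). Analyses
are restricted to autosomes labelled 1..29 (the caprine autosome count);
other labels are dropped at QC with a logged count.

Two QC tracks reflect standard practice. The *strict* track - used for the
relationship matrix, F_exH, diversity and structure - applies, in a fixed
order chosen so the report is deterministic: per-marker quality score
(default minimum 0.60, applied only when scores exist), marker call rate
(>= 0.90), sample call rate (>= 0.90, computed after marker removal), minor
allele frequency (>= 0.05) and a Hardy-Weinberg exact-test cut (p > 1e-5,
computed on pooled counts, matching a single joint run over all
populations). The *lenient* track - used for run detection - stops after
the call-rate filters: monomorphic and rare markers are informative inside
runs and removing them would bias run lengths. The HWE test is the standard
exact test on the conditional distribution of heterozygote counts given
allele counts, without mid-p correction; probabilities are built by the
ratio recurrence, and the suite checks them against full enumeration.

PLINK text (PED/MAP) and binary (BED/BIM/FAM, SNP-major, bit-exact) files
are read and written natively. Text files carry no allele orientation, so
the reader adopts "first allele observed = A2" unless an explicit allele
vector is given; `align_alleles()` reorients dosages between conventions.
All downstream statistics are orientation-invariant.

## Run calling

**ROH (sliding window).** Per sample and chromosome: a window of 50 SNPs
slides one SNP at a time; a window is a *hit* if it contains at most 1
heterozygous and at most 1 missing call; a SNP is *eligible* if at least 5%
of the windows covering it are hits. A passing interval must consist of
eligible SNPs, start and end on homozygous SNPs, contain no inter-marker
gap above 500 kb, span at least 1 Mb with at least 50 SNPs, have an average
density of at least one SNP per 100 kb (run-average semantics, i.e.
`length/n_snp <= 100 kb`), and contain at most 1 heterozygous call in total
(the run-level budget defaults to the window budget; a permissive mode that
drops the run-level budget is available). All numbers are parameters of
`roh_params()`.

The reported run set is defined as the *greedy left-to-right disjoint
selection over passing intervals*: repeatedly take the passing interval
with the leftmost start (ties resolved to the rightmost end) that starts
after the previously reported run. This definition was chosen because it is
simultaneously (a) what a left-to-right scanner produces, (b) a
well-defined function of the set of passing intervals that an independent
brute-force enumerator can compute, and (c) guaranteed non-overlapping.
Candidate generation is exact, including the rare case where an interval
fails the density bound while a sub-interval passes it (possible with
irregular spacing); the suite verifies exact equality with interval
enumeration on hundreds of random instances.

**ROHet (consecutive markers).** A candidate starts at a heterozygous SNP
and extends while at most 2 missing and at most 3 homozygous calls are
absorbed; it ends at the last heterozygous SNP within budget and is
reported if it has at least 15 SNPs spanning at least 500 kb. The same
greedy disjoint selection applies, so the scanner and the enumeration
oracle coincide here too.

**Length classes.** ROH: 1-2, 2-4, 4-8, > 8 Mb; ROHet: 0.5-1.0, 1.0-1.5,
1.5-2.0, > 2.0 Mb. Bins are half-open `[lo, hi)` - a run of exactly 2.0 Mb
is a "2-4 Mb" run - because boundary handling must be fixed somewhere and
the upper-class convention keeps the top class's lower edge inclusive.
Run coordinates are first/last marker positions (1-based inclusive);
`length = end - start + 1`: marker data carry no information beyond the
flanking markers.

## Inbreeding coefficients

* **F_ROH** = summed ROH length / L_TOTAL, where L_TOTAL is the summed
  per-chromosome span (last minus first marker position + 1) of the marker
  set the runs were called on - always recomputed, never a hard-coded
  constant. Class-wise variants partition the numerator, so they sum to the
  total exactly (a suite invariant at 1e-12).
* **F_G** = `G_ii - 1` from the VanRaden method-1 genomic relationship
  matrix `G = ZZ'/(2 sum p(1-p))` with `Z` the dosage matrix column-centered
  by `2p` and missing values imputed to the column mean (contributing zero).
  Centering matters: the uncentered cross-product of raw 0/1/2 dosages does
  not have the `F = G_ii - 1` interpretation; it is available behind
  `center = FALSE` for comparison only. Monomorphic markers are excluded
  from both `Z` and the scaling constant. Frequencies default to the pooled
  analysed samples (one joint run), configurable.
* **F_exH** = `(Obs_homo - Exp_homo) / (Total - Exp_homo)` per sample over
  its called genotypes, with the bias-corrected expectation
  `Exp_homo = sum_j (1 - 2 p_j (1 - p_j) n_j/(n_j - 1))`; markers with one
  called genotype are excluded. Monomorphic markers add one to both
  observed and expected counts and therefore cancel.
* **Heterozygosity coefficient** from ROHet: the default is summed ROHet
  length / L_TOTAL, mirroring F_ROH. The literature this quantity comes
  from is ambiguous about its definition, and reported magnitudes are not
  reproducible from segment-length tables alone; a second definition (the
  fraction of markers inside a ROHet) is therefore provided behind
  `definition = "snp_fraction"`, and neither is presented as a certified
  published formula. The two agree in ranking (Spearman > 0.9 in the
  suite's block-design check).

Pearson correlations among all coefficients, with t-based p-values, form
the correlation matrix; columns with zero variance (e.g. a structurally
empty length class) are dropped with a message.

## Hotspot islands

The incidence track records, per population and marker, the fraction of
genotyped samples whose run covers the marker (the denominator is the
genotyped count at that marker, not the population size). Threshold modes:

* `absolute` - e.g. 0.50: at least half the population in a run;
* `top_quantile` - the cutoff is the `ceiling(q m)`-th largest per-marker
  fraction, i.e. the value reached by exactly the top `q` share of markers
  (up to ties). A plain interpolated quantile would misbehave on sparse
  tracks - on 999 zeros and a single 1.0 a 0.1% tail must resolve to 1.0,
  not to an interpolated near-zero - and the rank-based cutoff is also how
  per-population thresholds are reported in practice (a "top 0.5%"
  threshold lands just above 50% incidence on a typical cohort);
* `combined` (ROH default) - the maximum of an absolute 0.50 and the top
  0.5% cutoff; ROHet hotspots use the top 0.1%.

Ties at the threshold are included (the comparison is `>=`, matching "at
least 50%"). Hotspot SNPs within 500 kb merge into one island (the run gap
constant reused, configurable); islands report bp bounds of their first and
last member SNP, plus both the peak and the mean member fraction, since
either may be wanted as the island's "percentage". Cross-population
overlaps are computed as interval intersections (via `IRanges`), reporting
every maximal region shared by at least two populations with its
contributing set. Annotation accepts BED (0-based half-open) or GFF3
(1-based) interval files through `rtracklayer`, which normalises
coordinates; features overlapping an island by at least 1 bp are reported
with the overlap length.

## Diversity and structure

Observed heterozygosity is the mean per-marker heterozygote fraction among
called samples; expected heterozygosity the mean of `2p(1-p)` (optionally
with the `n/(n-1)` correction); PN the fraction of markers polymorphic
within the population. IBS distance is `1 - mean(shared alleles)/2` with
pairwise deletion of missing calls; it is invariant under allele-label
flips. PCA runs on the column-centered (optionally standardised) dosage
matrix with mean imputation of missing calls - centered-only is the default,
the common population-structure choice. Neighbor-joining trees are built
with `ape::nj` (the standard implementation of the Saitou-Nei algorithm) at
sample or population level (population distances = mean between-population
sample distances); negative branch lengths, which can arise on non-additive
matrices, are optionally clamped to zero with the deficit moved to the
adjacent branches and the tree flagged. Trees export as Newick.

## Population comparisons

Per-sample run counts per length class are compared across populations with
one-way ANOVA plus Tukey HSD (studentized-range p-values via R's `ptukey`
machinery, Tukey-Kramer errors for unbalanced groups) and a compact letter
display built by the insert-and-absorb algorithm over the pairwise
significance matrix, with groups ordered by decreasing mean for
determinism. Counts are not normal, so a rank-based alternative
(Kruskal-Wallis with Holm-adjusted pairwise Wilcoxon tests) sits behind
`method = "kruskal"`; the parametric route is the default because that is
how such tables are conventionally produced. An all-equal or zero-variance
response yields one shared letter and a null global test rather than an
error.

## The simulator: what it emulates, and what it does not

`gene_drop()` drops founder haplotypes through an explicit pedigree:
founder alleles are drawn marker-wise from a truncated Beta(0.5, 0.5)
frequency distribution (U-shaped, as array frequency spectra tend to be,
truncated to [0.05, 0.95] so strict-QC retains most markers); gametes
recombine with Poisson crossover counts under a uniform 1 cM/Mb map
(Haldane, no interference - interference is irrelevant at array
resolution); each founder haplotype carries a unique label whose
transmission is tracked in bp segments, so autozygosity is known exactly
(segments below 10 kb, far below marker resolution, are dropped from the
truth). Missingness is applied last. Pedigree F is computed by the tabular
kinship method. Population histories: unrelated founder pairs (F = 0),
full-sib loops (F = 0.25), and generations of random mating in a finite
population (background relatedness; 20-30 generations of a 10-30 animal
population give the short-segment spectrum of ancient inbreeding).

Marker positions are *clustered* by default: inter-marker gaps are drawn
lognormal (sdlog 1.0 around a ~40 kb mean at the default density), matching
the strongly right-skewed spacing of real arrays, whose gaps span roughly
1 kb to 1 Mb. This is not cosmetic: with evenly spaced markers at 50 kb, a
50-SNP run can never span less than ~2.5 Mb and the 1-2 Mb length class -
the dominant class on real arrays - would be structurally empty. Dense
local stretches are what make short runs observable. Even and uniform
spacing remain available as options.

Planted islands overwrite genotypes for `round(f * n)` carriers (chosen by
the seeded RNG): a shared homozygous haplotype (drawn once from the founder
frequencies) for ROH islands, forced heterozygosity for ROHet islands.
Realized carrier fractions are recorded in the truth object; planted
genotypes are IBS-by-construction and deliberately *not* added to the IBD
truth, which tracks descent only.

Not emulated: linkage disequilibrium beyond what pedigree transmission
creates, array ascertainment bias, genotyping-error structure beyond
uniform missingness, sex chromosomes, real genetic maps, mutation, and
selection dynamics. Passing tests therefore demonstrate correctness of the
*methods* under known autozygosity, not calibration against any particular
real cohort.

## Validation design and problem sizes

The suite's end-to-end study uses 5 chromosomes x 50 Mb with 1,000
clustered markers each: a 200-sample cohort with pedigree F in {0, 0.25}
(100 founder-pair offspring, 100 full-sib offspring) plus a 60-sample
drifted population (14 founders, 30 generations) supplying the
short-segment end of the spectrum. On it the suite checks that group-mean
F_ROH lands within 0.05 of the pedigree expectation, that regressing F_ROH
on the true IBD fraction gives slope 1 +/- 0.1 and intercept within 0.03,
and that the correlation of total F_ROH with the > 8 Mb class exceeds that
with the 1-2 Mb class - the classic pattern of correlations falling with
segment length. Other checks: exact equality of both run callers with
brute-force interval enumeration on 500 random instances (up to 200 SNPs,
randomised parameters); HWE exact p-values against full enumeration for
all count triples up to n = 8; planted-island recovery (carrier fraction
0.6, absolute threshold 0.5) with >= 95% sensitivity and <= 5% false-call
replicates over 100 seeds; NJ topology and branch-length recovery from
additive matrices on 4-8 taxa (100 trees); Tukey family-wise error within
[0.03, 0.07] under a 5-group null over 2,000 simulations; and 100
text/binary PLINK round trips. These sizes keep the whole suite near a
minute on one core while leaving every estimate's Monte-Carlo error well
inside the asserted tolerances.

The `analysis/` scripts run the same stack as a narrative workflow on a
five-population cohort with planted shared and private islands, writing
every table under `results/`; `scripts/acceptance.R` recomputes the
headline quantities from scratch for any seed.

## Known limitations

* ROH semantics follow the PLINK-style flag family but are a from-scratch
  implementation with its own tie-break rule (greedy leftmost-start
  selection); ordering of equally valid overlapping candidates may differ
  from other tools in edge cases, though all constraint logic is
  enumeration-verified.
* The heterozygosity coefficient's published definition is ambiguous; both
  implemented variants are labelled as such.
* The simulator's drifted histories generate background relatedness by
  explicit pedigree only; very short ancient segments (below the marker
  resolution) are invisible to all ROH methods and are not a test target.
* Tukey letters assume the pairwise decision matrix is internally
  consistent; with pathological p-value patterns the insert-and-absorb
  display is still deterministic but may need more letters than the
  minimum.
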