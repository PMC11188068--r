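---
title: "Methods: benchmarking imputed ancient genomes and analysing runs of homozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking imputed ancient genomes and analysing runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoroh)
```

## The problem

Ancient genomes are usually sequenced at well below 1x coverage, which
rules out confident diploid genotype calls and, with them, most
individual-level population-genetic analyses. Genotype imputation from a
large phased reference panel can recover diploid genotypes from such
data, but its output must be validated before being trusted: per-class
genotyping error, non-reference discordance (NRD), r² against
high-coverage truth stratified by minor allele frequency, placement in
PCA space, and the fidelity of downstream runs-of-homozygosity (ROH)
calls. `paleoroh` implements that whole validation and analysis loop on
synthetic data with planted truth, so every stage is testable without
any sequencing data.

## The synthetic world

`simulate_panel()` builds a haplotype panel by mosaic copying: founder
haplotypes are drawn per site from a U-shaped Beta(0.4, 0.4) frequency
distribution (many rare variants, as in real panels), and every other
haplotype copies from the founders with per-bp template switching
(default 1e-6) and per-site mutation (1e-3). Per-site panel allele
frequency is the mean over haplotypes — `site_density` defaults to one
segregating site per 10 kb, the density at which a 50-SNP ROH window
spans 500 kb.

`sample_individual()` draws the two haplotypes of a diploid individual
site-by-site under Hardy–Weinberg at the panel frequency. Sites are
therefore independent: linkage disequilibrium, recombination maps and
demography are deliberate non-goals. The consequence for testing is
that background (non-planted) autozygosity essentially never occurs, so
planted ROH are the only true ROH — exactly what a truth set should be.

`plant_roh()` duplicates one haplotype over the other inside each
tract, which makes every overlapping site homozygous without changing
allele frequencies; `froh_truth` equals merged planted length divided
by genome length by construction. Tract lengths are drawn as a mix of
short (0.6–1.6 Mb) and long (1.6–4 Mb) segments, matching the 1.6 Mb
short/long analysis boundary. A `forbidden` region list supports
planting shared ROH-free "deserts"; a fixed 200 kb margin is kept
around forbidden regions because a called segment's boundary is the
outermost *eligible* SNP and can legitimately extend a few SNPs past
the planted tract — without the margin that spill can place one base
pair of called ROH inside a region the generator means to keep empty.

`corrupt_genotypes()` turns truth into an "imputed-like" callset. Each
genotype flips with probability (class error) × (site factor), where
the class errors default to 2% (hom-ref), 5% (het) and 10% (hom-alt) —
the ordering observed for imputed low-coverage genomes, where hom-alt
errors are roughly twice the het errors and hom-ref/het errors sit
below 5% at usable coverages. The site factor is a unit-mean Gamma
jitter times a ×3 multiplier at sites with folded MAF < 0.05 (rare
variants impute worse). The emitted INFO score is a *monotone* map of
the site factor, `INFO = clamp(1 − 2.5 × class-scale × factor)`: noise
enters through the jitter, not through the map, so filtering at a
higher INFO cutoff provably never enriches for error in the synthetic
world. Depth is Poisson around the model coverage (the simplest model
consistent with shotgun data); pseudohaploid copies sample one allele
per site and are missing with probability `exp(-coverage)`, the Poisson
zero class.

What a green test does establish: the formulas, gates, window
arithmetic, matching rules and permutation machinery are implemented
correctly, and parameters planted in this world are recovered. What it
does not establish: performance on real aDNA, where LD, reference bias,
contamination and deamination damage all act; the paper-scale headline
numbers (e.g. r² > 0.9 at 0.5x) are properties of a 1,519-sample real
panel and are out of scope by design.

## Filtering rules

`validation_filter()` applies, in fixed order (QUAL ≥ 30, depth,
allele balance), the rules used to clean high-coverage validation
genomes: sites with depth above twice the genome-wide mean or below
`max(mean/3, 8)` are removed, and heterozygous sites where either
allele carries less than 15% or more than 85% of reads are removed.
The order fixes the removal tally: each site is attributed to the first
rule it fails. `post_imputation_filter()` keeps folded MAF ≥ 0.01 and
INFO ≥ 0.8; both boundaries are *inclusive* — the sources say "below
0.8" and "cutoff of 0.01", which we read as keep-at-the-boundary,
consistent with community convention. `restrict_to_transversions()`
drops C↔T and G↔A pairs, the classes confounded by post-mortem
deamination.

## Concordance scoring

`tally_confusion()` aligns truth and imputed callsets on
chromosome/position and counts a 3×3 matrix over hom-ref/het/hom-alt,
gated on the truth side by depth ≥ 8 and genotype posterior ≥ 0.9 so
that shaky validation genotypes are not booked as imputation errors.
NRD is

$$\mathrm{NRD} = \frac{e_{RR}+e_{RA}+e_{AA}}{e_{RR}+e_{RA}+e_{AA}+m_{RA}+m_{AA}}$$

with $e$ the per-truth-class mismatches and $m$ the het/hom-alt
matches; the concordant hom-ref cell — the overwhelming majority of any
real callset — cancels out entirely. Empty truth classes report `NA`,
never a silent 0. `r2_by_maf_bin()` uses squared Pearson correlation of
hard-called doses (the convention of the standard concordance tool) in
left-open/right-closed folded-MAF bins with edges 0, 0.001, 0.002,
0.005, 0.01, 0.05, 0.1, 0.2, 0.5, swept over INFO cutoffs
{none, 0.8, 0.9, 0.95}; bins with fewer than two usable sites or
constant dose are flagged `NA`.

## The ROH caller

`call_roh()` implements the sliding-window heuristic with the ancient-
DNA parameterisation: windows of 50 consecutive SNPs pass with at most
1 heterozygous and 5 missing calls; a SNP is eligible when at least 5%
of the windows covering it pass; maximal runs of eligible SNPs, split
at inter-SNP gaps over 500 kb, are emitted when they hold ≥ 50 SNPs,
span ≥ 500 kb, and average at most 50 kb per SNP. Three contract points
the upstream tool leaves undocumented are fixed here and validated
against a brute-force enumerator rather than against the external
binary: (i) only fully contained windows count, so near chromosome ends
the hit-fraction denominator shrinks; (ii) emitted boundaries are the
outermost eligible SNPs, not extended into flanking gaps (output is
0-based half-open, BED-style); (iii) heterozygous or missing SNPs
inside a run stay inside — called loci are regions of low diversity
rather than strictly unbroken homozygosity, because the window cap does
not bound hets per segment. One caveat: "lowering `window_threshold`
never removes a called base pair" is not a theorem under the density
cap (newly eligible sparse SNPs can push a segment over 50 kb/SNP); it
holds on realistic tracks and is tested as an empirical property.

## ROH accuracy

`length_confusion()` classifies every base of the evaluated genome as
ROH/non-ROH in both sets (TP/FP/FN/TN partition the genome exactly);
`segment_confusion()` matches segments one-to-one by any-overlap,
greedily in coordinate order — the simplest rule that caps TP at both
set sizes, adopted because the source leaves segment matching
undefined. `overlap_metrics()` reports F1, sensitivity, specificity,
FDR, MCC and nMCC = (MCC+1)/2, which maps the chance level to 0.5 and
perfect overlap to 1. Metrics are micro-averaged over pooled tallies,
undefined ratios are `NA`, and the degenerate perfect cases are
special-cased so that identical sets give *exactly* 1.

## Inbreeding and cohort comparison

`froh()` is total merged ROH length over total autosome length (the
denominator is user-supplied chromosome sizes — the source never states
its own), split at 1.6 Mb with the boundary segment counted as long
(the defining sentence reads "≥ 1.6 Mb"; a contradictory "≤" appears
once elsewhere and is treated as a typo). `rank_sum_compare()` runs a
Mann–Whitney U test: for combined n ≤ 20 the null is enumerated
exhaustively over labelings of the pooled midranks and the two-sided
p-value is the probability of a U at least as far from n_A·n_B/2 as
observed (with ties this is well-defined and gives p = 1 for identical
groups); larger samples use the tie-corrected normal approximation with
continuity correction, matching `wilcox.test(exact = FALSE)`.

## ROH landscape, deserts and enrichment

`window_prevalence()` tiles the genome into 500-kb windows (final
partial window kept at true width) and scores, per cohort, the
percentage of samples with ≥ 1 bp of ROH in each window.
`exclude_outlier_windows()` drops windows whose mean depth falls
outside mean ± 2 sd across windows — a copy-number/mapping-artefact
guard — and windows without imputed sites; with Gaussian depth this
removes ~5% of windows, mirroring the ~98% retention seen in practice.
`detect_deserts()` requires prevalence *strictly* below 5% in both the
ancient and the modern cohort, among retained windows only; a window at
exactly 5% is not a desert. `desert_enrichment()` takes genes
overlapping a desert window as candidates, restricts the background to
genes overlapping retained windows, computes a hypergeometric
over-representation p per category, and controls the family-wise error
rate by redrawing candidate sets of the observed size with probability
proportional to gene length (the gene-length correction; uniform
drawing is a switch) — a category's FWER is the fraction of permuted
sets whose minimum p across categories is at most the category's
observed p.

## PCA projection

`fit_pca()` standardizes each polymorphic site by mean dose and
√(p(1−p)), with the shrunken frequency p = (count+1)/(2n+2) so
near-fixed sites cannot blow up the scale; missing reference genotypes
are mean-imputed; the space comes from an SVD of the standardized
matrix. `project_sample()` least-squares-fits the standardized
non-missing doses of a (possibly very sparse) sample onto the loadings
restricted to those sites, so a complete reference sample reproduces
its own coordinates to numerical tolerance. The "sum of weighted PC
distances" is undefined in the source; we adopt

$$d(a,b) = \sum_{k=1}^{10} \frac{\lambda_k}{\sum_{j\le 10}\lambda_j}\,|a_k-b_k|,$$

eigenvalue-share weights with absolute per-component differences —
symmetric, zero iff equal on the first 10 PCs, and configurable in
principle (√λ or unweighted Euclidean are the obvious alternatives).

## Pipelines and reproducibility

`run_benchmark()` sweeps coverage levels 0.05–2x. "Downsampling" is
emulated by a coverage→error table (no reads exist at desk scale):
hom-ref/het errors fall below 5% from 0.5x, hom-alt stays roughly
double the het error. `run_analysis()` synthesizes cohorts with planted
F_ROH, calls ROH, and emits F_ROH summaries, pairwise rank-sum tests,
the window track, desert BED and enrichment TSV. A single top-level
seed spawns independent per-stage substreams (`derive_seed()`), so any
stage can be re-run in isolation and whole report bundles are
byte-identical under a fixed seed; `manifest.json` records seed, a
config hash and per-file MD5 checksums. Figures are presentation-only
and carry no acceptance weight; YAML configs are unsupported in this
build (no YAML parser in the target environment — JSON is).

## Numerical and degenerate-input choices

Undefined rates and correlations are always `NA` plus a reason, never
0. Genome-scale base-pair tallies are held as doubles before products
(the four-cell MCC overflows 32-bit integers on a 100-Mb genome).
Chromosomes with fewer SNPs than one window warn and yield no calls.
Empty cohorts, all-missing samples, zero-site panels and
out-of-bounds planted tracts raise contract errors naming the
violated precondition.
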