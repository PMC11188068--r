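# paleoroh

Benchmarking of genotype imputation for low-coverage (ancient) genomes,
and analysis of runs of homozygosity (ROH) — implemented end to end on
synthetic data with planted truth, so every stage is testable offline.

## Who this is for

Population geneticists working with ancient DNA who impute diploid
genotypes from a phased reference panel and need to know (a) how
trustworthy those genotypes are before using them, and (b) what the
downstream inbreeding and ROH-landscape analyses look like once they
are trusted. The package provides both halves:

* **Benchmark mode** — simulate a truth genome with planted autozygous
  tracts, corrupt it into an "imputed-like" callset at a chosen
  coverage, and score it: per-class genotyping error, non-reference
  discordance, r² by minor-allele-frequency bin under INFO-score
  cutoffs, ROH-overlap accuracy, and weighted PC-distance to the truth
  projection.
* **Analysis mode** — call ROH per sample with a PLINK-style sliding
  window, compute F_ROH inbreeding coefficients with a 1.6 Mb
  short/long decomposition, compare cohorts with exact Mann–Whitney
  tests, map ROH prevalence in 500-kb windows, detect ROH deserts
  (< 5% prevalence in both an ancient and a modern cohort), and test
  gene categories for desert enrichment with a hypergeometric test and
  a 1000-permutation family-wise error rate.

## Core statistics

Non-reference discordance over the 3×3 genotype confusion matrix
(classes hom-ref RR, het RA, hom-alt AA; `e` = mismatches at a truth
class, `m` = diagonal matches):

    NRD = (eRR + eRA + eAA) / (eRR + eRA + eAA + mRA + mAA)

ROH overlap accuracy at base-pair resolution uses the four-cell
confusion matrix (TP/FP/FN/TN partition the genome), F1, MCC, and the
normalised MCC, `nMCC = (MCC + 1)/2`, where 0.5 is a random prediction
and 1 perfect overlap. The inbreeding coefficient is
`F_ROH = total merged ROH length / total autosome length`.

## Worked example

```r
library(paleoroh)

cfg <- run_config("benchmark", outdir = "bench_out", seed = 42,
                  coverage_levels = c(0.1, 0.5, 2),
                  chrom_lengths = c(chr1 = 10e6), site_density = 2e-4,
                  n_reference = 15)
tabs <- run_benchmark(cfg)
round(tabs$concordance, 4)
#>   coverage err_hom_ref err_het err_hom_alt    nrd
#> 1      0.1      0.1302  0.2122      0.5903 0.5328
#> 2      0.5      0.0304  0.0289      0.1898 0.1650
#> 3      2.0      0.0049  0.0064      0.0891 0.0704
round(tabs$roh_accuracy, 4)
#>   coverage f1_length nmcc_length sensitivity specificity    fdr f1_segment
#> 1      0.1        NA          NA      0.0000      1.0000     NA         NA
#> 2      0.5    0.9519      0.9741      0.9081      1.0000 0.0000          1
#> 3      2.0    0.9283      0.9613      0.9995      0.9829 0.1334          1
```

Reading the output: at an emulated 0.1x, imputed genotypes are too
noisy to call any ROH (sensitivity 0, F1 undefined because nothing is
predicted); from 0.5x the hom-ref and het error rates drop below 5%,
NRD falls accordingly, and the planted ROH are recovered with
length-based nMCC above 0.96. Hom-alt errors stay the highest class
throughout, as they do for real imputed ancient genomes. All tables,
plus `r2_by_maf.tsv` and `pc_distance.tsv` and a `manifest.json` with
seed/config hash/output checksums, are written to `bench_out/`.

A command-line front-end with the same two modes ships in
`inst/cli/paleoroh.R`:

```sh
Rscript inst/cli/paleoroh.R analysis --seed 7 --outdir analysis_out
```

## The methods vignette

`vignettes/paleoroh-methods.Rmd` documents the synthetic model and its
deliberate simplifications, every threshold with its rationale, the
caller's edge-case contracts, and the numerical choices for degenerate
inputs.
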