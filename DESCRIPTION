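Package: paleoroh
Title: Imputation Accuracy and Runs-of-Homozygosity Analysis for
    Low-Coverage Ancient Genomes
Version: 0.1.0
Authors@R:
    person("paleoroh", "developers", email = "paleoroh@example.org",
           role = c("aut", "cre"))
Description: Tools to benchmark genotype imputation of low-coverage
    (ancient) genomes and to analyse runs of homozygosity (ROH).
    Provides a synthetic diploid genotype simulator with planted
    autozygous tracts and an imputation-like corruption model; site and
    genotype filters for validation and post-imputation callsets;
    concordance scoring (per-class genotyping error rates,
    non-reference discordance, r-squared stratified by minor allele
    frequency under INFO-score cutoffs); a sliding-window ROH caller;
    segment- and length-based ROH overlap accuracy metrics (F1, MCC,
    normalised MCC, sensitivity, specificity, FDR); F_ROH inbreeding
    coefficients with short/long decomposition and exact rank-sum
    cohort comparisons; windowed ROH prevalence, desert detection and
    hypergeometric category enrichment with permutation family-wise
    error rates; and least-squares PCA projection of sparse samples
    with weighted principal-component distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
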