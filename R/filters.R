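# Site and genotype filters for validation callsets, reference-panel
# sites and post-imputation cleanup.

#' Filter thresholds
#'
#' Bundles the thresholds used across the filtering rules: a site QUAL
#' floor, the depth rules for validation genomes (lower bound
#' `max(mean/3, 8)`, upper bound twice the genome-wide mean), the
#' heterozygous allele-balance band, the post-imputation folded-MAF and
#' INFO floors, and the panel missingness ceiling. Boundaries are
#' inclusive for MAF/INFO (a site at exactly the cutoff is kept).
#'
#' @param min_qual site QUAL floor for validation callsets.
#' @param het_balance length-2 band of acceptable minor-read fractions at
#'   heterozygous sites.
#' @param maf_min folded minor-allele-frequency floor.
#' @param info_min INFO-score floor.
#' @param max_missing_fraction maximum per-site missing-genotype fraction
#'   for reference-panel sites.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(min_qual = 30, het_balance = c(0.15, 0.85),
                        maf_min = 0.01, info_min = 0.8,
                        max_missing_fraction = 0.05) {
  if (het_balance[1] < 0 || het_balance[2] > 1 ||
      het_balance[1] >= het_balance[2])
    stop_contract("het_balance must satisfy 0 <= lower < upper <= 1")
  if (maf_min < 0 || maf_min > 0.5)
    stop_contract("maf_min must lie in [0, 0.5]")
  structure(list(min_qual = min_qual, het_balance = het_balance,
                 maf_min = maf_min, info_min = info_min,
                 max_missing_fraction = max_missing_fraction),
            class = "filter_spec")
}

#' Filter a high-coverage validation callset
#'
#' Applies, in a fixed order so removal tallies are reproducible
#' (QUAL, then depth, then allele balance):
#' \enumerate{
#'   \item sites with QUAL below `spec$min_qual` (only when the table
#'     carries QUAL);
#'   \item sites whose depth exceeds `2 * mean_doc` or falls below
#'     `max(mean_doc / 3, 8)`;
#'   \item heterozygous sites at which either allele is supported by less
#'     than 15\% or more than 85\% of the reads.
#' }
#' Each removed site is attributed to the first rule it fails.
#'
#' @param calls a single-sample [genotype_table()] with `dp` and `ad_alt`.
#' @param mean_doc genome-wide mean depth of coverage of the sample.
#' @param spec a [filter_spec()].
#' @return list with `table` (the filtered `genotype_table`) and `tally`
#'   (data.frame rule / sites_removed).
#' @export
validation_filter <- function(calls, mean_doc, spec = filter_spec()) {
  stopifnot(inherits(calls, "genotype_table"))
  if (is.null(calls$dp) || is.null(calls$ad_alt))
    stop_contract("validation filter needs DP and AD annotations")
  if (n_samples(calls) != 1L)
    stop_contract("validation filter operates on one sample at a time")
  dp <- as.numeric(calls$dp[, 1])
  gt <- calls$gt[, 1]
  ad_alt <- as.numeric(calls$ad_alt[, 1])
  removed <- rep(NA_character_, n_sites(calls))
  if (!is.null(calls$sites$qual)) {
    fail <- !is.na(calls$sites$qual) & calls$sites$qual < spec$min_qual
    removed[fail] <- "qual"
  }
  lower <- max(mean_doc / 3, 8)
  fail_dp <- is.na(removed) & (dp > 2 * mean_doc | dp < lower)
  removed[fail_dp] <- "depth"
  frac_alt <- ifelse(dp > 0, ad_alt / dp, NA)
  fail_bal <- is.na(removed) & !is.na(gt) & gt == 1L & !is.na(frac_alt) &
    (frac_alt < spec$het_balance[1] | frac_alt > spec$het_balance[2])
  removed[fail_bal] <- "balance"
  tally <- data.frame(
    rule = c("qual", "depth", "balance"),
    sites_removed = c(sum(removed == "qual", na.rm = TRUE),
                      sum(removed == "depth", na.rm = TRUE),
                      sum(removed == "balance", na.rm = TRUE)),
    stringsAsFactors = FALSE)
  list(table = calls[is.na(removed)], tally = tally)
}

#' Post-imputation site filter
#'
#' Retains sites with folded minor allele frequency at least `maf_min`
#' and INFO score at least `info_min` (both boundaries inclusive).
#'
#' @param calls a [genotype_table()] with `af` and `info` annotations.
#' @param spec a [filter_spec()].
#' @return the filtered `genotype_table`.
#' @export
post_imputation_filter <- function(calls, spec = filter_spec()) {
  stopifnot(inherits(calls, "genotype_table"))
  if (is.null(calls$sites$af) || is.null(calls$sites$info))
    stop_contract("post-imputation filter needs AF and INFO annotations")
  keep <- site_maf(calls) >= spec$maf_min & calls$sites$info >= spec$info_min
  calls[keep]
}

is_transition <- function(ref, alt) {
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C") |
    (ref == "G" & alt == "A") | (ref == "A" & alt == "G")
}

#' Restrict a callset to transversion sites
#'
#' Removes transition sites (C<->T, G<->A), which are confounded by
#' post-mortem cytosine deamination in ancient DNA; all other ref/alt
#' pairs are kept.
#'
#' @param calls a [genotype_table()].
#' @return the filtered `genotype_table`.
#' @export
restrict_to_transversions <- function(calls) {
  stopifnot(inherits(calls, "genotype_table"))
  ok <- calls$sites$ref %in% c("A", "C", "G", "T") &
    calls$sites$alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop_contract("non-ACGT alleles at %d site(s)", sum(!ok))
  calls[!is_transition(calls$sites$ref, calls$sites$alt)]
}

#' Reference-panel site filter
#'
#' Retains biallelic SNPs whose fraction of missing genotypes across
#' panel samples does not exceed `max_missing_fraction`.
#'
#' @param calls a multi-sample [genotype_table()].
#' @param spec a [filter_spec()].
#' @return list with `table` (filtered) and `n_removed`.
#' @export
panel_site_filter <- function(calls, spec = filter_spec()) {
  stopifnot(inherits(calls, "genotype_table"))
  miss <- rowMeans(is.na(calls$gt))
  keep <- miss <= spec$max_missing_fraction
  list(table = calls[keep], n_removed = sum(!keep))
}
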