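# Genotype concordance between an imputed callset and high-coverage
# truth: 3x3 confusion tallies, per-class error rates, non-reference
# discordance (NRD), and r-squared stratified by MAF bin under INFO-score
# sweeps.

#' Default folded-MAF bin edges
#'
#' Left-open / right-closed bins on folded minor allele frequency ending
#' at 0.5, the stratification conventionally used when benchmarking
#' low-coverage imputation.
#' @export
MAF_BIN_EDGES <- c(0, 0.001, 0.002, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5)

#' Truth-callset gate for concordance scoring
#'
#' Only truth genotypes supported by at least `min_depth` reads and a
#' genotype posterior of at least `min_posterior` enter the confusion
#' tallies, so poorly supported validation genotypes do not masquerade as
#' imputation errors.
#'
#' @param min_depth minimum truth read depth (default 8).
#' @param min_posterior minimum truth genotype posterior (default 0.9).
#' @return an object of class `concordance_gate`.
#' @export
concordance_gate <- function(min_depth = 8, min_posterior = 0.9) {
  if (min_depth < 0 || min_posterior < 0 || min_posterior > 1)
    stop_contract("invalid gate thresholds")
  structure(list(min_depth = min_depth, min_posterior = min_posterior),
            class = "concordance_gate")
}

site_key <- function(x) paste(x$sites$chrom, x$sites$pos, sep = ":")

#' Tally a 3x3 truth-vs-imputed genotype confusion matrix
#'
#' Aligns the two callsets on chromosome/position, applies the truth-side
#' gate, and counts genotype pairs over the classes hom-ref (RR), het
#' (RA) and hom-alt (AA). Sites with a missing imputed genotype are
#' excluded from the tallies and reported.
#'
#' @param truth,imputed single-sample [genotype_table()]s; `truth` must
#'   carry `dp` (and `prob` if the gate uses a posterior).
#' @param gate a [concordance_gate()].
#' @return an object of class `confusion_counts`: the 3x3 integer matrix
#'   (rows = truth class, columns = called class) with attributes
#'   `n_gated_out` and `n_missing_imputed`.
#' @export
tally_confusion <- function(truth, imputed, gate = concordance_gate()) {
  stopifnot(inherits(truth, "genotype_table"),
            inherits(imputed, "genotype_table"))
  if (n_samples(truth) != 1L || n_samples(imputed) != 1L)
    stop_contract("concordance is scored one sample at a time")
  ki <- match(site_key(truth), site_key(imputed))
  keep <- !is.na(ki)
  if (!any(keep)) stop_contract("no overlapping sites between callsets")
  tg <- truth$gt[keep, 1]
  ig <- imputed$gt[ki[keep], 1]
  pass <- !is.na(tg)
  if (!is.null(truth$dp)) {
    pass <- pass & !is.na(truth$dp[keep, 1]) &
      truth$dp[keep, 1] >= gate$min_depth
  } else if (gate$min_depth > 0) {
    stop_contract("gate requires truth depth but table has no DP")
  }
  if (!is.null(truth$prob))
    pass <- pass & truth$prob[keep, 1] >= gate$min_posterior
  n_gated_out <- sum(!pass)
  tg <- tg[pass]; ig <- ig[pass]
  miss <- is.na(ig)
  cls <- c("RR", "RA", "AA")
  tab <- table(factor(tg[!miss], levels = 0:2),
               factor(ig[!miss], levels = 0:2))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(truth = cls, called = cls))
  structure(m, class = c("confusion_counts", class(m)),
            n_gated_out = n_gated_out, n_missing_imputed = sum(miss))
}

#' Build confusion counts from named cells
#'
#' Convenience constructor from the diagonal matches (`mRR`, `mRA`,
#' `mAA`) and the per-truth-class mismatch totals (`eRR`, `eRA`, `eAA`).
#' Mismatches at a truth class are split arbitrarily between the two
#' wrong called classes; every metric in this package depends only on the
#' row sums and diagonal, so the split is immaterial.
#'
#' @param mRR,mRA,mAA diagonal (match) counts.
#' @param eRR,eRA,eAA mismatch counts at truth hom-ref, het, hom-alt.
#' @return a `confusion_counts` matrix.
#' @export
confusion_counts <- function(mRR = 0, mRA = 0, mAA = 0,
                             eRR = 0, eRA = 0, eAA = 0) {
  m <- matrix(0, 3, 3, dimnames = list(truth = c("RR", "RA", "AA"),
                                       called = c("RR", "RA", "AA")))
  diag(m) <- c(mRR, mRA, mAA)
  m["RR", "RA"] <- eRR
  m["RA", "RR"] <- eRA
  m["AA", "RA"] <- eAA
  structure(m, class = c("confusion_counts", class(m)),
            n_gated_out = 0L, n_missing_imputed = 0L)
}

#' Per-class genotyping error rates and non-reference discordance
#'
#' Class error = mismatches at that truth class / truth-class total
#' (reported `NA` when a truth class is empty, never silently 0).
#' Non-reference discordance excludes the concordant hom-ref cell, which
#' dominates real callsets:
#' \deqn{NRD = (eRR + eRA + eAA) / (eRR + eRA + eAA + mRA + mAA)}
#'
#' @param counts a `confusion_counts` matrix.
#' @return list with `err_hom_ref`, `err_het`, `err_hom_alt`, `nrd`, and
#'   the named cells used.
#' @export
error_rates <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (sum(counts) == 0) stop_contract("empty confusion counts")
  row_tot <- rowSums(counts)
  mism <- row_tot - diag(counts)
  rate <- ifelse(row_tot > 0, mism / row_tot, NA_real_)
  e_sum <- sum(mism)
  denom <- e_sum + counts["RA", "RA"] + counts["AA", "AA"]
  nrd <- if (denom > 0) e_sum / denom else NA_real_
  list(err_hom_ref = rate[["RR"]], err_het = rate[["RA"]],
       err_hom_alt = rate[["AA"]], nrd = nrd,
       eRR = unname(mism["RR"]), eRA = unname(mism["RA"]),
       eAA = unname(mism["AA"]),
       mRA = counts["RA", "RA"], mAA = counts["AA", "AA"])
}

maf_bin_of <- function(maf, edges = MAF_BIN_EDGES) {
  cut(maf, breaks = edges, include.lowest = FALSE, right = TRUE)
}

#' Imputation r-squared stratified by MAF bin under INFO cutoffs
#'
#' For each folded-MAF bin and each INFO cutoff, computes the squared
#' Pearson correlation between truth and imputed hard-called doses over
#' sites passing the truth gate and the cutoff. Bins with fewer than two
#' usable sites, or with constant dose in either callset, are flagged
#' with `r2 = NA` rather than zeroed.
#'
#' @param truth,imputed single-sample [genotype_table()]s; `imputed`
#'   must carry `af` and `info`.
#' @param bins numeric vector of bin edges (default [MAF_BIN_EDGES]).
#' @param info_cutoffs numeric vector of INFO cutoffs; `NA` means no
#'   cutoff.
#' @param gate a [concordance_gate()] applied to the truth callset.
#' @return data.frame with columns `bin_low`, `bin_high`, `info_cutoff`,
#'   `n_sites`, `r2`.
#' @export
r2_by_maf_bin <- function(truth, imputed, bins = MAF_BIN_EDGES,
                          info_cutoffs = c(NA, 0.8, 0.9, 0.95),
                          gate = concordance_gate()) {
  stopifnot(inherits(truth, "genotype_table"),
            inherits(imputed, "genotype_table"))
  if (is.null(imputed$sites$af) || is.null(imputed$sites$info))
    stop_contract("imputed table needs AF and INFO annotations")
  if (any(diff(bins) <= 0)) stop_contract("bin edges must strictly increase")
  ki <- match(site_key(truth), site_key(imputed))
  keep <- which(!is.na(ki))
  if (!length(keep)) stop_contract("no overlapping sites between callsets")
  tg <- truth$gt[keep, 1]
  idx <- ki[keep]
  ig <- imputed$gt[idx, 1]
  maf <- pmin(imputed$sites$af, 1 - imputed$sites$af)[idx]
  inf <- imputed$sites$info[idx]
  pass <- !is.na(tg) & !is.na(ig)
  if (!is.null(truth$dp))
    pass <- pass & truth$dp[keep, 1] >= gate$min_depth
  if (!is.null(truth$prob))
    pass <- pass & truth$prob[keep, 1] >= gate$min_posterior
  bin <- maf_bin_of(maf, bins)
  out <- list()
  for (co in info_cutoffs) {
    sel <- pass & (if (is.na(co)) TRUE else inf >= co)
    for (b in levels(bin)) {
      i <- sel & !is.na(bin) & bin == b
      n <- sum(i)
      r2 <- NA_real_
      if (n >= 2 && stats::var(tg[i]) > 0 && stats::var(ig[i]) > 0)
        r2 <- stats::cor(tg[i], ig[i])^2
      edges_b <- bins[match(b, levels(bin)) + c(0, 1)]
      out[[length(out) + 1L]] <- data.frame(
        bin_low = edges_b[1], bin_high = edges_b[2], info_cutoff = co,
        n_sites = n, r2 = r2)
    }
  }
  do.call(rbind, out)
}
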