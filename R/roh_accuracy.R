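# Accuracy of predicted ROH against truth ROH, at base-pair and segment
# resolution, with the confusion-matrix metrics used for benchmarking.

#' Length-based (base-pair) ROH confusion tallies
#'
#' Treats each base of the evaluated genome as ROH / non-ROH in both the
#' predicted and the truth segment set: `tp_bp` is the overlap,
#' `fp_bp` predicted-only, `fn_bp` truth-only, and `tn_bp` the remainder;
#' the four tallies always partition `genome_length`.
#'
#' @param pred,truth BED-like data.frames (chrom, start, end; 0-based
#'   half-open), each internally non-overlapping (merge first).
#' @param genome_length total evaluated genome length in bp (at least the
#'   coverage of either set).
#' @return an object of class `length_confusion`: list with `tp_bp`,
#'   `fp_bp`, `fn_bp`, `tn_bp`.
#' @export
length_confusion <- function(pred, truth, genome_length) {
  pg <- assert_disjoint(pred, "predicted segments")
  tg <- assert_disjoint(truth, "truth segments")
  tp <- as.numeric(sum(as.numeric(
    GenomicRanges::width(GenomicRanges::intersect(pg, tg)))))
  fp <- sum(as.numeric(GenomicRanges::width(GenomicRanges::setdiff(pg, tg))))
  fn <- sum(as.numeric(GenomicRanges::width(GenomicRanges::setdiff(tg, pg))))
  tn <- genome_length - tp - fp - fn
  if (tn < 0)
    stop_contract("genome_length smaller than the union of the segment sets")
  structure(list(tp_bp = tp, fp_bp = fp, fn_bp = fn, tn_bp = tn),
            class = "length_confusion")
}

#' Segment-based ROH confusion tallies
#'
#' Matches predictions to truths one-to-one by any-overlap, greedily in
#' coordinate order: each prediction (sorted by chromosome, start) is
#' paired with the first not-yet-matched overlapping truth segment.
#' `tp` = matched pairs, `fp` = unmatched predictions, `fn` = unmatched
#' truths; `tp` can never exceed either set size.
#'
#' @inheritParams length_confusion
#' @return an object of class `segment_confusion`: list with `tp`, `fp`,
#'   `fn`.
#' @export
segment_confusion <- function(pred, truth) {
  pg <- assert_disjoint(pred, "predicted segments")
  tg <- assert_disjoint(truth, "truth segments")
  pg <- BiocGenerics::sort(pg)
  tg <- BiocGenerics::sort(tg)
  hits <- GenomicRanges::findOverlaps(pg, tg)
  matched_t <- logical(length(tg))
  tp <- 0L
  for (p in seq_len(length(pg))) {
    cand <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == p]
    cand <- cand[!matched_t[cand]]
    if (length(cand)) {
      matched_t[min(cand)] <- TRUE
      tp <- tp + 1L
    }
  }
  structure(list(tp = tp, fp = length(pg) - tp, fn = sum(!matched_t)),
            class = "segment_confusion")
}

#' Overlap accuracy metrics from confusion tallies
#'
#' Computes sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1
#' `2*(precision*sensitivity)/(precision+sensitivity)`, and FDR
#' `FP/(TP+FP)`; for length-based tallies (which carry TN) also
#' specificity `TN/(TN+FP)`, the Matthews correlation coefficient from
#' the standard four-cell formula, and its normalisation
#' `nMCC = (MCC+1)/2` (0.5 = random prediction, 1 = perfect overlap).
#' Undefined ratios are reported as `NA`, never silently 0; the F1 of two
#' disjoint non-empty sets is 0.
#'
#' @param counts a `length_confusion` or `segment_confusion`.
#' @return list with `f1`, `mcc`, `nmcc`, `sensitivity`, `specificity`,
#'   `precision`, `fdr` (TN-based entries are `NA` for segment tallies).
#' @export
overlap_metrics <- function(counts) {
  if (inherits(counts, "length_confusion")) {
    tp <- as.numeric(counts$tp_bp); fp <- as.numeric(counts$fp_bp)
    fn <- as.numeric(counts$fn_bp); tn <- as.numeric(counts$tn_bp)
  } else if (inherits(counts, "segment_confusion")) {
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- NA_real_
  } else stop_contract("counts must be a length_confusion or segment_confusion")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  fdr <- ratio(fp, tp + fp)
  spec <- if (is.na(tn)) NA_real_ else ratio(tn, tn + fp)
  f1 <- if (is.na(sens) || is.na(prec)) NA_real_
        else if (sens + prec == 0) 0
        else 2 * prec * sens / (prec + sens)
  mcc <- NA_real_
  if (!is.na(tn)) {
    dens <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    if (all(dens > 0)) {
      if (fp == 0 && fn == 0) mcc <- 1        # perfect agreement, exactly
      else if (tp == 0 && tn == 0) mcc <- -1  # perfect disagreement
      else mcc <- (tp * tn - fp * fn) /
        (sqrt(dens[1]) * sqrt(dens[2]) * sqrt(dens[3]) * sqrt(dens[4]))
    }
  }
  list(f1 = f1, mcc = mcc,
       nmcc = if (is.na(mcc)) NA_real_ else (mcc + 1) / 2,
       sensitivity = sens, specificity = spec, precision = prec, fdr = fdr)
}

#' Place non-overlapping segments uniformly at random
#'
#' Utility for calibration experiments: drops `n` equal-length,
#' non-overlapping segments uniformly on a single chromosome using the
#' order-statistics construction (draw starts in the shrunken interval,
#' sort, then re-inflate), which is exact rather than rejection-based.
#'
#' @param n number of segments.
#' @param seg_length segment length in bp.
#' @param genome_length chromosome length in bp.
#' @param chrom chromosome name.
#' @return BED-like data.frame of `n` disjoint segments.
#' @export
random_segments <- function(n, seg_length, genome_length, chrom = "chr1") {
  if (n * seg_length > genome_length)
    stop_contract("segments do not fit in the genome")
  slack <- genome_length - n * seg_length
  starts <- sort(floor(runif(n, 0, slack + 1)))
  starts <- starts + (seq_len(n) - 1) * seg_length
  data.frame(chrom = chrom, start = starts, end = starts + seg_length,
             stringsAsFactors = FALSE)
}
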