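# F_ROH inbreeding coefficients and exact rank-sum cohort comparisons.

#' ROH-based inbreeding coefficient with short/long decomposition
#'
#' F_ROH is the total merged ROH length divided by the total genome
#' length (the sum of the autosome lengths being analysed). Segments are
#' additionally partitioned at `long_cutoff` into short (< cutoff) and
#' long (>= cutoff; a segment of exactly the cutoff counts as long)
#' blocks, which reflect older background versus recent close
#' inbreeding; `froh_all = froh_short + froh_long` by construction.
#'
#' @param segments BED-like data.frame of one sample's ROH segments
#'   (merged before tallying, so the result is invariant to splitting a
#'   segment into abutting pieces).
#' @param genome_length total genome length in bp, or a named vector of
#'   chromosome lengths to be summed.
#' @param long_cutoff short/long boundary in bp (default 1.6 Mb).
#' @param sample_id optional sample label carried into the summary.
#' @return data.frame (one row) with `sample`, `n_roh`, `total_roh_bp`,
#'   `froh_all`, `froh_short`, `froh_long`.
#' @export
froh <- function(segments, genome_length, long_cutoff = 1.6e6,
                 sample_id = NA_character_) {
  if (length(genome_length) > 1) genome_length <- sum(genome_length)
  if (genome_length <= 0) stop_contract("genome_length must be positive")
  seg <- merge_segments(check_segments(segments, "ROH segments"))
  len <- if (nrow(seg)) seg$end - seg$start else numeric()
  if (sum(len) > genome_length)
    stop_contract("segments exceed the stated genome length")
  long <- len >= long_cutoff
  data.frame(sample = sample_id, n_roh = nrow(seg),
             total_roh_bp = sum(len),
             froh_all = sum(len) / genome_length,
             froh_short = sum(len[!long]) / genome_length,
             froh_long = sum(len[long]) / genome_length,
             stringsAsFactors = FALSE)
}

#' F_ROH summaries for a set of samples with metadata
#'
#' @param segments_by_sample BED-like data.frame with an additional
#'   `sample` column.
#' @param genome_length as in [froh()].
#' @param metadata optional data.frame with a `sample` column (plus e.g.
#'   `cohort`, `age_bp`, `region`), joined onto the summaries. Samples
#'   present in the metadata but without segments get zero F_ROH.
#' @param long_cutoff short/long boundary in bp.
#' @return data.frame, one row per sample.
#' @export
froh_summary <- function(segments_by_sample, genome_length, metadata = NULL,
                         long_cutoff = 1.6e6) {
  ids <- unique(c(as.character(segments_by_sample$sample),
                  if (!is.null(metadata)) as.character(metadata$sample)))
  rows <- lapply(ids, function(s) {
    seg <- segments_by_sample[segments_by_sample$sample == s, , drop = FALSE]
    froh(seg[, c("chrom", "start", "end")], genome_length,
         long_cutoff = long_cutoff, sample_id = s)
  })
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) out <- merge(out, metadata, by = "sample",
                                       all.x = TRUE, sort = FALSE)
  out
}

#' Mann-Whitney rank-sum comparison of two cohorts
#'
#' Reports the U statistic in min orientation (`min(U_A, U_B)`) and a
#' two-sided p-value. For combined sample sizes up to `exact_max` the
#' null distribution is enumerated exhaustively over all group labelings
#' of the pooled midranks, and the two-sided p-value is the fraction of
#' labelings at least as extreme as observed (|U - n_A n_B / 2| >=
#' observed); with n_A + n_B above `exact_max` a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param a,b numeric vectors of e.g. per-sample F_ROH values; both
#'   non-empty.
#' @param exact_max largest combined size for the exact enumeration.
#' @return list with `u` (min orientation), `u_a`, `p`, `method`.
#' @export
rank_sum_compare <- function(a, b, exact_max = 20) {
  if (!length(a) || !length(b))
    stop_contract("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  center <- na * nb / 2
  if (n <= exact_max) {
    combs <- utils::combn(n, na)
    u_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - center) >= abs(u_a - center) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u_a - center
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(u = min(u_a, u_b), u_a = u_a, p = p, method = method)
}

#' Pairwise rank-sum tests between cohorts
#'
#' @param summary a [froh_summary()] result with a `cohort` column.
#' @param value column of `summary` to compare (default `"froh_all"`).
#' @return data.frame with one row per unordered cohort pair: `cohort_a`,
#'   `cohort_b`, `n_a`, `n_b`, `u`, `p`.
#' @export
pairwise_rank_sum <- function(summary, value = "froh_all") {
  if (!"cohort" %in% names(summary))
    stop_contract("summary needs a cohort column")
  cohorts <- unique(as.character(summary$cohort))
  if (length(cohorts) < 2) stop_contract("need at least two cohorts")
  pairs <- utils::combn(cohorts, 2)
  rows <- apply(pairs, 2, function(pr) {
    va <- summary[[value]][summary$cohort == pr[1]]
    vb <- summary[[value]][summary$cohort == pr[2]]
    ts <- rank_sum_compare(va, vb)
    data.frame(cohort_a = pr[1], cohort_b = pr[2],
               n_a = length(va), n_b = length(vb),
               u = ts$u, p = ts$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
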