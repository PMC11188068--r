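# Sliding-window runs-of-homozygosity caller.
#
# Mirrors the window heuristic popularized by PLINK --homozyg: windows of
# `window_snp` consecutive SNPs pass if they contain at most `window_het`
# heterozygous and `window_missing` missing calls; a SNP is eligible when
# the fraction of passing windows covering it reaches `window_threshold`;
# maximal runs of eligible SNPs (split at large gaps) become segments if
# they satisfy the SNP-count, length and density floors. Only fully
# contained windows are counted: near chromosome ends the hit-fraction
# denominator is the smaller number of covering windows. Emitted segment
# boundaries are the outermost eligible SNPs (BED: 0-based, half-open).
# Heterozygous SNPs inside a candidate run stay inside the segment, so
# called loci are regions of low diversity rather than strictly unbroken
# homozygosity; missing calls count toward the window cap but never break
# a run.

#' ROH caller parameters
#'
#' Defaults correspond to the settings recommended for ancient samples:
#' 50-SNP windows tolerating 1 heterozygous and 5 missing calls, 5\%
#' window-hit threshold, and segment floors of 50 SNPs, 500 kb, maximum
#' 500 kb gap between consecutive SNPs and at most 50 kb per SNP.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het maximum heterozygous calls in a passing window.
#' @param window_missing maximum missing calls in a passing window.
#' @param window_threshold minimum fraction of passing covering windows
#'   for a SNP to be eligible.
#' @param min_snp minimum SNPs per emitted segment.
#' @param min_kb minimum segment span in kb.
#' @param max_gap_kb maximum gap between consecutive SNPs of one segment.
#' @param max_density_kb_per_snp maximum span/SNP ratio in kb per SNP.
#' @return an object of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50, window_het = 1, window_missing = 5,
                       window_threshold = 0.05, min_snp = 50, min_kb = 500,
                       max_gap_kb = 500, max_density_kb_per_snp = 50) {
  if (window_threshold <= 0 || window_threshold > 1)
    stop_contract("window_threshold must lie in (0, 1]")
  vals <- c(window_snp, window_missing + 1, min_snp, min_kb, max_gap_kb,
            max_density_kb_per_snp)
  if (any(vals <= 0)) stop_contract("ROH parameters must be positive")
  structure(list(window_snp = as.integer(window_snp),
                 window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 window_threshold = window_threshold,
                 min_snp = as.integer(min_snp), min_kb = min_kb,
                 max_gap_kb = max_gap_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp),
            class = "roh_params")
}

#' Extract a per-SNP ROH track from a genotype table
#'
#' @param calls a [genotype_table()].
#' @param sample sample name or index (default first sample).
#' @return data.frame with `chrom`, `pos`, `gt` (dose; `NA` missing) and
#'   `ref`/`alt` columns, sorted by chromosome and position.
#' @export
roh_track <- function(calls, sample = 1L) {
  stopifnot(inherits(calls, "genotype_table"))
  data.frame(chrom = calls$sites$chrom, pos = calls$sites$pos,
             gt = calls$gt[, sample],
             ref = calls$sites$ref, alt = calls$sites$alt,
             stringsAsFactors = FALSE)
}

#' Call runs of homozygosity with a sliding SNP window
#'
#' @param track data.frame with columns `chrom`, `pos` (strictly
#'   increasing per chromosome) and `gt` (alt dose 0/1/2, `NA` missing).
#'   Heterozygous means `gt == 1`.
#' @param params an [roh_params()].
#' @return data.frame of segments: `chrom`, `start`, `end` (0-based,
#'   half-open, delimited by the outermost eligible SNPs), `n_snps`,
#'   `length_kb`; non-overlapping and sorted. A chromosome with fewer
#'   SNPs than the window size yields no calls, with a warning.
#' @export
call_roh <- function(track, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  if (!all(c("chrom", "pos", "gt") %in% names(track)))
    stop_contract("track must have chrom/pos/gt columns")
  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    if (any(diff(t$pos) <= 0))
      stop_contract("positions not strictly increasing on %s", ch)
    seg <- call_roh_chrom(t$pos, t$gt, params)
    if (is.null(seg)) {
      warning(sprintf("chromosome %s has fewer than %d SNPs; no calls",
                      ch, params$window_snp), call. = FALSE)
      next
    }
    if (nrow(seg)) {
      seg$chrom <- ch
      out[[length(out) + 1L]] <- seg[, c("chrom", "start", "end",
                                         "n_snps", "length_kb")]
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      length_kb = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Core single-chromosome caller; returns NULL when n < window size.
call_roh_chrom <- function(pos, gt, params) {
  n <- length(pos)
  w <- params$window_snp
  if (n < w) return(NULL)
  het <- !is.na(gt) & gt == 1L
  mis <- is.na(gt)
  W <- n - w + 1L
  ch <- cumsum(het); cm <- cumsum(mis)
  het_w <- ch[w:n] - c(0, ch)[seq_len(W)]
  mis_w <- cm[w:n] - c(0, cm)[seq_len(W)]
  pass <- het_w <= params$window_het & mis_w <= params$window_missing
  cp <- c(0, cumsum(pass))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(W, i)
  hits <- cp[hi + 1L] - cp[lo]
  eligible <- hits / (hi - lo + 1L) >= params$window_threshold
  idx <- which(eligible)
  if (!length(idx))
    return(data.frame(start = numeric(), end = numeric(),
                      n_snps = integer(), length_kb = numeric()))
  new_run <- c(TRUE, diff(idx) > 1L |
                 diff(pos[idx]) > params$max_gap_kb * 1000)
  grp <- cumsum(new_run)
  first <- idx[!duplicated(grp)]
  last <- idx[!duplicated(grp, fromLast = TRUE)]
  n_snps <- as.integer(tabulate(grp))
  start <- pos[first] - 1
  end <- pos[last]
  len <- end - start
  ok <- n_snps >= params$min_snp & len >= params$min_kb * 1000 &
    (len / 1000) / n_snps <= params$max_density_kb_per_snp
  data.frame(start = start[ok], end = end[ok], n_snps = n_snps[ok],
             length_kb = len[ok] / 1000)
}

#' Call ROH on transversion sites only
#'
#' Removes transition sites (C<->T, G<->A) from the track, then runs
#' [call_roh()]; used to guard against ancient-DNA deamination damage.
#'
#' @param track as in [call_roh()], additionally with `ref` and `alt`
#'   columns.
#' @param params an [roh_params()].
#' @return as [call_roh()].
#' @export
call_roh_transversions <- function(track, params = roh_params()) {
  if (!all(c("ref", "alt") %in% names(track)))
    stop_contract("transversion mode needs ref/alt columns in the track")
  ok <- track$ref %in% c("A", "C", "G", "T") &
    track$alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop_contract("non-ACGT alleles at %d site(s)", sum(!ok))
  call_roh(track[!is_transition(track$ref, track$alt), , drop = FALSE],
           params)
}
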