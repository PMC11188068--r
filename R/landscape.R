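# Windowed ROH prevalence across cohorts, depth-outlier window
# exclusion, ROH-desert detection, and gene-category enrichment with a
# permutation family-wise error rate.

#' Tile a genome into fixed-width windows
#'
#' Windows are 0-based half-open `[k*size, (k+1)*size)` tiles of each
#' chromosome; the final partial window is retained at its true width.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param window_size window width in bp (default 500 kb).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
tile_windows <- function(chrom_lengths, window_size = 5e5) {
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-window ROH prevalence by cohort
#'
#' A sample counts as carrying ROH in a window iff any of its segments
#' overlaps the window by at least one base; prevalence is the
#' percentage of the cohort's samples carrying ROH in the window.
#'
#' @param segments_by_sample BED-like data.frame with a `sample` column
#'   (segments of every sample across cohorts).
#' @param cohorts named character vector mapping sample -> cohort label;
#'   every cohort must have at least one sample.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window_size window width in bp.
#' @return an object of class `window_track`: data.frame of windows with
#'   one `prev_<cohort>` column per cohort (percent, 0-100), plus
#'   `excluded` (logical) and `exclude_reason` columns (all retained
#'   initially; see [exclude_outlier_windows()]).
#' @export
window_prevalence <- function(segments_by_sample, cohorts, chrom_lengths,
                              window_size = 5e5) {
  if (!length(cohorts)) stop_contract("no cohort labels supplied")
  if (is.null(names(cohorts)))
    stop_contract("cohorts must be a named vector (sample -> cohort)")
  win <- tile_windows(chrom_lengths, window_size)
  wgr <- segments_to_granges(win)
  labels <- unique(unname(cohorts))
  for (lab in labels) {
    members <- names(cohorts)[cohorts == lab]
    if (!length(members)) stop_contract("cohort '%s' is empty", lab)
    carriers <- matrix(FALSE, nrow = nrow(win), ncol = length(members))
    for (j in seq_along(members)) {
      seg <- segments_by_sample[segments_by_sample$sample == members[j], ,
                                drop = FALSE]
      if (!nrow(seg)) next
      hit <- GenomicRanges::findOverlaps(wgr, segments_to_granges(seg))
      carriers[unique(S4Vectors::queryHits(hit)), j] <- TRUE
    }
    win[[paste0("prev_", lab)]] <- 100 * rowMeans(carriers)
  }
  win$excluded <- FALSE
  win$exclude_reason <- NA_character_
  class(win) <- c("window_track", class(win))
  win
}

#' Exclude depth-outlier and empty windows
#'
#' Flags windows whose mean depth lies outside mean +/- 2 standard
#' deviations (both computed across windows) -- a guard against copy
#' number variants and mapping artefacts -- and windows containing no
#' imputed sites. Excluded windows carry no prevalence (`NA`).
#'
#' @param track a [window_prevalence()] result.
#' @param window_depth numeric vector, mean depth per window (same order
#'   as the track).
#' @param window_sites optional integer vector of imputed-site counts per
#'   window; windows with zero sites are excluded regardless of depth.
#' @return the track with `excluded`, `exclude_reason` filled in and
#'   prevalence columns of excluded windows set to `NA`.
#' @export
exclude_outlier_windows <- function(track, window_depth,
                                    window_sites = NULL) {
  stopifnot(inherits(track, "window_track"))
  if (length(window_depth) != nrow(track))
    stop_contract("window_depth must have one value per window")
  mu <- mean(window_depth); s <- stats::sd(window_depth)
  out_depth <- if (is.na(s) || s == 0) rep(FALSE, nrow(track))
    else window_depth < mu - 2 * s | window_depth > mu + 2 * s
  no_sites <- if (is.null(window_sites)) rep(FALSE, nrow(track))
    else window_sites == 0
  track$excluded <- out_depth | no_sites
  track$exclude_reason[out_depth] <- "depth"
  track$exclude_reason[no_sites] <- "no_sites"
  prev_cols <- grep("^prev_", names(track), value = TRUE)
  for (cc in prev_cols) track[[cc]][track$excluded] <- NA_real_
  track
}

#' Detect ROH deserts
#'
#' A retained window is a desert iff the ROH prevalence is strictly
#' below `threshold` percent in \emph{both} named cohorts (a window at
#' exactly the threshold is not a desert).
#'
#' @param track a [window_prevalence()] (optionally after
#'   [exclude_outlier_windows()]).
#' @param ancient,modern cohort labels to compare.
#' @param threshold prevalence threshold in percent (default 5).
#' @return the desert windows as a BED-like data.frame (subset of the
#'   track rows).
#' @export
detect_deserts <- function(track, ancient, modern, threshold = 5) {
  stopifnot(inherits(track, "window_track"))
  ca <- paste0("prev_", ancient); cm <- paste0("prev_", modern)
  if (!all(c(ca, cm) %in% names(track)))
    stop_contract("track lacks a prevalence column for '%s' or '%s'",
                  ancient, modern)
  keep <- !track$excluded & !is.na(track[[ca]]) & !is.na(track[[cm]]) &
    track[[ca]] < threshold & track[[cm]] < threshold
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-category enrichment in ROH deserts with permutation FWER
#'
#' Candidate genes are background genes overlapping a desert window by at
#' least one base; the background is restricted to genes overlapping at
#' least one retained (non-excluded) window. Each category with at least
#' one background gene gets a hypergeometric over-representation p-value
#' `P(X >= k)`. The family-wise error rate corrects for multiple testing
#' and category interdependency: candidate sets of the observed size are
#' redrawn `n_permutations` times with probability proportional to gene
#' length (the gene-length correction), all category p-values are
#' recomputed, and a category's FWER is the fraction of permuted sets
#' whose \emph{minimum} p-value is at most the category's observed
#' p-value.
#'
#' @param track a window track after [exclude_outlier_windows()].
#' @param deserts desert windows from [detect_deserts()].
#' @param genes BED-like data.frame with a `gene` column.
#' @param gene2cat data.frame with columns `gene`, `category`.
#' @param n_permutations number of permuted candidate sets (default 1000).
#' @param length_weighted draw permuted candidates proportional to gene
#'   length (default) or uniformly.
#' @param seed integer seed for the permutations.
#' @return data.frame with `category`, `n_candidate_genes`,
#'   `n_background_genes`, `p`, `fwer`, sorted by p.
#' @export
desert_enrichment <- function(track, deserts, genes, gene2cat,
                              n_permutations = 1000,
                              length_weighted = TRUE, seed = 1L) {
  stopifnot(inherits(track, "window_track"))
  genes <- check_segments(genes, "genes")
  if (!"gene" %in% names(genes)) stop_contract("genes needs a gene column")
  retained <- track[!track$excluded, , drop = FALSE]
  ggr <- segments_to_granges(genes)
  in_bg <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(ggr, segments_to_granges(retained))))
  bg <- genes[sort(in_bg), , drop = FALSE]
  if (!nrow(bg)) stop_contract("no background genes overlap retained windows")
  bgr <- segments_to_granges(bg)
  cand <- rep(FALSE, nrow(bg))
  if (nrow(deserts))
    cand[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(bgr, segments_to_granges(deserts))))] <- TRUE
  cats <- split(gene2cat$gene, gene2cat$category)
  member <- matrix(FALSE, nrow = nrow(bg), ncol = length(cats),
                   dimnames = list(NULL, names(cats)))
  for (j in seq_along(cats)) member[, j] <- bg$gene %in% cats[[j]]
  k_bg <- colSums(member)
  absent <- k_bg == 0
  if (any(absent)) {
    warning(sprintf("%d categor(ies) have no background gene; skipped",
                    sum(absent)), call. = FALSE)
    member <- member[, !absent, drop = FALSE]
    k_bg <- k_bg[!absent]
  }
  if (!ncol(member)) stop_contract("no scorable categories")
  N <- nrow(bg); n_cand <- sum(cand)
  hyper_p <- function(is_cand) {
    k <- colSums(member & is_cand)
    stats::phyper(k - 1, k_bg, N - k_bg, sum(is_cand), lower.tail = FALSE)
  }
  p_obs <- hyper_p(cand)
  w <- if (length_weighted) (bg$end - bg$start) else rep(1, N)
  min_p <- with_seed(derive_seed(seed, "enrichment"), {
    vapply(seq_len(n_permutations), function(i) {
      perm <- rep(FALSE, N)
      perm[sample.int(N, n_cand, prob = w)] <- TRUE
      min(hyper_p(perm))
    }, numeric(1))
  })
  fwer <- vapply(p_obs, function(p) mean(min_p <= p), numeric(1))
  out <- data.frame(category = colnames(member),
                    n_candidate_genes = colSums(member & cand),
                    n_background_genes = k_bg,
                    p = p_obs, fwer = fwer, stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
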