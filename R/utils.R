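# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' A single top-level seed drives every stochastic stage of the package.
#' Each stage derives its own seed from the top-level seed plus a stage
#' tag, so stages can be re-run in isolation while remaining jointly
#' reproducible. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer top-level seed.
#' @param tag Character stage tag (e.g. `"panel"`, `"corrupt"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- 0
  for (k in seq_along(codes)) h <- (h * 131 + codes[k]) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_contract <- function(...) stop(sprintf(...), call. = FALSE)

# Validate a BED-like segment data.frame (0-based half-open intervals).
check_segments <- function(seg, what = "segments") {
  if (is.null(seg) || nrow(seg) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(seg)))
    stop_contract("%s must have columns chrom/start/end", what)
  if (any(seg$end <= seg$start))
    stop_contract("%s contain empty or inverted intervals", what)
  seg
}

segments_to_granges <- function(seg) {
  seg <- check_segments(seg)
  if (nrow(seg) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(seg$chrom,
                         IRanges::IRanges(start = seg$start + 1, end = seg$end))
}

granges_to_segments <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Error if intervals within one set overlap each other.
assert_disjoint <- function(seg, what = "segments") {
  gr <- segments_to_granges(seg)
  if (length(gr) == 0L) return(invisible(gr))
  if (sum(GenomicRanges::width(gr)) != sum(GenomicRanges::width(GenomicRanges::reduce(gr))))
    stop_contract("%s overlap within one set; merge them first", what)
  invisible(gr)
}

# Merge intervals (union) and return BED-like frame sorted by chrom/start.
merge_segments <- function(seg) {
  gr <- GenomicRanges::reduce(segments_to_granges(seg))
  out <- granges_to_segments(gr)
  out[order(out$chrom, out$start), , drop = FALSE]
}

total_segment_length <- function(seg) {
  m <- merge_segments(seg)
  if (nrow(m) == 0L) 0 else sum(m$end - m$start)
}
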