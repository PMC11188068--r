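# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files are shipped.

# Small handmade genotype table (3 samples, explicit annotations).
toy_table <- function() {
  sites <- data.frame(
    chrom = rep("chr1", 6),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = c("A", "C", "G", "T", "A", "G"),
    alt = c("G", "T", "A", "A", "T", "C"),
    af = c(0.10, 0.50, 0.90, 0.005, 0.30, 0.95),
    info = c(0.99, 0.85, 0.80, 0.95, 0.60, 0.92),
    qual = c(50, 40, 29, 60, 35, 45),
    stringsAsFactors = FALSE)
  gt <- matrix(c(0L, 1L, 2L, 0L, NA, 1L,
                 1L, 1L, 0L, 2L, 0L, 0L,
                 2L, 0L, 1L, 1L, 1L, 2L), ncol = 3)
  dp <- matrix(10L, nrow = 6, ncol = 3)
  ad <- matrix(as.integer(gt / 2 * 10), ncol = 3)
  ad[is.na(ad)] <- 0L
  genotype_table(sites, gt, dp = dp, ad_alt = ad,
                 samples = c("alpha", "beta", "gamma"),
                 chrom_lengths = c(chr1 = 1e6))
}

# A truth genome built directly from raw doses (no panel machinery), so
# tests can control class composition exactly. Positions are 10 bp apart.
raw_truth <- function(gt, af = NULL, chrom_len = NULL) {
  m <- length(gt)
  if (is.null(af)) af <- rep(0.5, m)
  structure(list(
    sites = data.frame(chrom = "chr1", pos = seq_len(m) * 10L,
                       ref = "A", alt = "C", af = af,
                       stringsAsFactors = FALSE),
    gt = as.integer(gt),
    hap1 = as.integer(gt >= 1), hap2 = as.integer(gt == 2),
    planted_segments = data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), stringsAsFactors = FALSE),
    froh_truth = 0,
    chrom_lengths = c(chr1 = chrom_len %||% (m * 10 + 10))),
    class = "truth_genome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard small synthetic chain used by several files.
small_chain <- function(seed = 101, target_froh = 0.1,
                        chrom_lengths = c(chr1 = 10e6),
                        site_density = 2e-4, coverage = 0.5) {
  panel <- simulate_panel(panel_config(
    n_haplotypes = 40, chrom_lengths = chrom_lengths,
    site_density = site_density, seed = seed))
  ind <- sample_individual(panel, seed = seed + 1)
  truth <- plant_roh(ind, target_froh = target_froh, seed = seed + 2)
  model <- corruption_model(coverage = coverage, seed = seed + 3)
  list(panel = panel, truth = truth,
       truth_tab = truth_table(truth, seed = seed + 4),
       imputed = corrupt_genotypes(truth, model))
}

# Random ROH-caller track for oracle-equivalence trials: mixture of
# homozygous stretches and noisy background so all caller rules fire.
random_track <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample.int(n * 2000, n))
  p_het <- 0.25
  gt <- sample(c(0L, 1L, 2L), n, replace = TRUE,
               prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2))
  # carve a few homozygous stretches of random length
  for (k in seq_len(sample(0:3, 1))) {
    a <- sample.int(n, 1)
    b <- min(n, a + sample(20:200, 1))
    gt[a:b] <- sample(c(0L, 2L), b - a + 1, replace = TRUE)
  }
  gt[runif(n) < 0.03] <- NA
  data.frame(chrom = "chr1", pos = pos, gt = gt, stringsAsFactors = FALSE)
}

bed_cols <- c("chrom", "start", "end")
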