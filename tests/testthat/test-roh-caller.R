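test_that("a long homozygous stretch yields one full-span segment", {
  pos <- seq(10000, by = 10000, length.out = 1000)
  track <- data.frame(chrom = "chr1", pos = pos, gt = 0L)
  seg <- call_roh(track)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 1000)
  expect_equal(seg$start, pos[1] - 1)
  expect_equal(seg$end, pos[1000])
  oracle <- oracle_call_roh(pos, rep(0L, 1000), roh_params())
  expect_equal(seg[, c("start", "end", "n_snps")],
               oracle[, c("start", "end", "n_snps")], ignore_attr = TRUE)
})

test_that("an all-heterozygous chromosome yields no segments", {
  track <- data.frame(chrom = "chr1",
                      pos = seq(1000, by = 1000, length.out = 500), gt = 1L)
  expect_equal(nrow(call_roh(track)), 0)
})

test_that("a 49-SNP homozygous run flanked by heterozygosity is rejected", {
  gt <- c(rep(1L, 200), rep(0L, 49), rep(1L, 200))
  pos <- seq(20000, by = 20000, length.out = length(gt))
  seg <- call_roh(data.frame(chrom = "chr1", pos = pos, gt = gt))
  expect_equal(nrow(seg), 0)
  # the same construction with 120 homozygous SNPs is accepted
  gt2 <- c(rep(1L, 200), rep(0L, 120), rep(1L, 200))
  pos2 <- seq(20000, by = 20000, length.out = length(gt2))
  seg2 <- call_roh(data.frame(chrom = "chr1", pos = pos2, gt = gt2))
  expect_equal(nrow(seg2), 1)
  # edge SNPs of the run lose eligibility to het-heavy covering windows
  expect_gte(seg2$n_snps, 110)
})

test_that("undersized chromosomes warn and yield no calls", {
  track <- data.frame(chrom = "chr1", pos = 1:10 * 100L, gt = 0L)
  expect_warning(seg <- call_roh(track), "fewer than")
  expect_equal(nrow(seg), 0)
})

test_that("caller equals the brute-force oracle on random tracks", {
  params <- roh_params()
  for (i in 1:60) {
    track <- random_track(n = sample(60:1500, 1), seed = 9000 + i)
    got <- call_roh(track, params)
    want <- oracle_call_roh(track$pos, track$gt, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want))
      expect_equal(got[, c("start", "end", "n_snps")],
                   want[, c("start", "end", "n_snps")], ignore_attr = TRUE)
  }
})

test_that("oracle equivalence holds under varied parameters", {
  alt_params <- roh_params(window_snp = 20, window_het = 2,
                           window_missing = 2, window_threshold = 0.1,
                           min_snp = 20, min_kb = 100, max_gap_kb = 100,
                           max_density_kb_per_snp = 100)
  for (i in 1:30) {
    track <- random_track(n = sample(40:800, 1), seed = 4000 + i)
    got <- call_roh(track, alt_params)
    want <- oracle_call_roh(track$pos, track$gt, alt_params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want))
      expect_equal(got[, c("start", "end", "n_snps")],
                   want[, c("start", "end", "n_snps")], ignore_attr = TRUE)
  }
})

test_that("segments never overlap and never exceed the chromosome span", {
  n_multi <- 0
  params <- roh_params(min_kb = 100)
  for (i in 1:20) {
    track <- random_track(n = 2000, seed = 300 + i)
    seg <- call_roh(track, params)
    if (nrow(seg) == 0) next
    expect_lte(sum(seg$end - seg$start), max(track$pos))
    if (nrow(seg) >= 2) {
      n_multi <- n_multi + 1
      expect_true(all(seg$start[-1] >= seg$end[-nrow(seg)]))
    }
  }
  expect_gt(n_multi, 0)
})

test_that("lowering the window threshold never removes called bases", {
  loose <- roh_params(window_threshold = 0.01)
  strict <- roh_params(window_threshold = 0.2)
  for (i in 1:10) {
    track <- random_track(n = 1500, seed = 600 + i)
    a <- call_roh(track, strict)
    b <- call_roh(track, loose)
    ga <- GenomicRanges::reduce(GenomicRanges::GRanges(
      a$chrom, IRanges::IRanges(a$start + 1, a$end)))
    gb <- GenomicRanges::reduce(GenomicRanges::GRanges(
      b$chrom, IRanges::IRanges(b$start + 1, b$end)))
    uncovered <- GenomicRanges::setdiff(ga, gb)
    expect_equal(sum(GenomicRanges::width(uncovered)), 0)
  }
})

test_that("planted segments >= 1 Mb are recovered at >= 0.95 reciprocal overlap", {
  panel <- simulate_panel(panel_config(
    n_haplotypes = 60, chrom_lengths = c(chr1 = 60e6),
    site_density = 2.5e-4, founder_af_beta = c(0.8, 0.8), seed = 13))
  ind <- sample_individual(panel, seed = 14)
  seg <- data.frame(chrom = "chr1", start = c(5e6, 20e6, 40e6),
                    end = c(6.5e6, 23e6, 41.2e6))
  truth <- plant_roh(ind, segments = seg)
  tab <- genotype_table(truth$sites, matrix(truth$gt, ncol = 1),
                        chrom_lengths = truth$chrom_lengths)
  tab <- tab[site_maf(tab) >= 0.05]
  called <- call_roh(roh_track(tab))
  for (k in seq_len(nrow(seg))) {
    ov <- pmin(called$end, seg$end[k]) - pmax(called$start, seg$start[k])
    j <- which.max(ov)
    reciprocal <- min(ov[j] / (seg$end[k] - seg$start[k]),
                      ov[j] / (called$end[j] - called$start[j]))
    expect_gte(reciprocal, 0.95)
  }
})

test_that("transversion mode equals full mode on transition-free tracks", {
  track <- random_track(n = 800, seed = 12)
  track$ref <- "A"; track$alt <- "T"
  expect_equal(call_roh_transversions(track), call_roh(track))
})

test_that("segments supported only by transitions vanish in transversion mode", {
  n <- 600
  pos <- seq(5000, by = 5000, length.out = n)
  gt <- rep(1L, n)
  gt[200:400] <- 0L  # homozygous run
  ref <- rep("A", n); alt <- rep("T", n)
  ref[200:400] <- "C"; alt[200:400] <- "T"  # run carried by transitions
  track <- data.frame(chrom = "chr1", pos = pos, gt = gt,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  expect_gte(nrow(call_roh(track)), 1)
  expect_equal(nrow(call_roh_transversions(track)), 0)
})

test_that("mixed toy tracks match the oracle in both modes", {
  params <- roh_params(window_snp = 25, min_snp = 25, min_kb = 100)
  for (i in 1:10) {
    track <- random_track(n = 700, seed = 7000 + i)
    set.seed(7100 + i)
    nt <- c("A", "C", "G", "T")
    track$ref <- sample(nt, nrow(track), replace = TRUE)
    track$alt <- vapply(track$ref, function(r) sample(nt[nt != r], 1), "")
    got <- call_roh_transversions(track, params)
    keep <- !((track$ref == "C" & track$alt == "T") |
                (track$ref == "T" & track$alt == "C") |
                (track$ref == "G" & track$alt == "A") |
                (track$ref == "A" & track$alt == "G"))
    want <- oracle_call_roh(track$pos[keep], track$gt[keep], params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want))
      expect_equal(got[, c("start", "end", "n_snps")],
                   want[, c("start", "end", "n_snps")], ignore_attr = TRUE)
  }
})
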