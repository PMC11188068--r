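test_that("single-founder panel without mutation is monomorphic", {
  cfg <- panel_config(n_haplotypes = 4, n_founders = 1, mutation_rate = 0,
                      chrom_lengths = c(chr1 = 1e6), site_density = 1e-4,
                      seed = 5)
  panel <- simulate_panel(cfg)
  expect_true(all(pmin(panel$sites$af, 1 - panel$sites$af) == 0))
})

test_that("panel simulation is deterministic given the seed", {
  cfg <- panel_config(n_haplotypes = 30, chrom_lengths = c(chr1 = 2e6),
                      site_density = 2e-4, seed = 42)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  cfg2 <- panel_config(n_haplotypes = 30, chrom_lengths = c(chr1 = 2e6),
                       site_density = 2e-4, seed = 43)
  expect_false(identical(simulate_panel(cfg), simulate_panel(cfg2)))
})

test_that("panel AF equals brute-force allele counting", {
  cfg <- panel_config(n_haplotypes = 200, chrom_lengths = c(chr1 = 1e8),
                      site_density = 1e-4, seed = 9)
  panel <- simulate_panel(cfg)
  expect_equal(nrow(panel$sites), 10000)
  expect_equal(panel$sites$af, oracle_af(panel$haplotypes))
})

test_that("invalid panel configs are rejected", {
  expect_error(panel_config(n_haplotypes = 0), "haplotype")
  expect_error(panel_config(chrom_lengths = c(chr1 = -5)), "lengths")
  expect_error(panel_config(mutation_rate = 1.5), "rates")
  expect_error(
    simulate_panel(panel_config(chrom_lengths = c(chr1 = 100),
                                site_density = 1e-6)),
    "zero sites")
})

test_that("positions are strictly increasing per chromosome", {
  panel <- simulate_panel(panel_config(
    n_haplotypes = 10, chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    site_density = 5e-4, seed = 3))
  for (ch in c("chr1", "chr2"))
    expect_true(all(diff(panel$sites$pos[panel$sites$chrom == ch]) > 0))
})

test_that("plant_roh with target 0 leaves the individual unchanged", {
  panel <- simulate_panel(panel_config(n_haplotypes = 20,
                                       chrom_lengths = c(chr1 = 5e6),
                                       site_density = 1e-4, seed = 7))
  ind <- sample_individual(panel, seed = 2)
  tg <- plant_roh(ind, target_froh = 0, seed = 3)
  expect_equal(nrow(tg$planted_segments), 0)
  expect_identical(tg$gt, ind$hap1 + ind$hap2)
  expect_equal(tg$froh_truth, 0)
})

test_that("explicit segments give froh_truth by construction", {
  panel <- simulate_panel(panel_config(n_haplotypes = 20,
                                       chrom_lengths = c(chr1 = 100e6),
                                       site_density = 1e-5, seed = 7))
  ind <- sample_individual(panel, seed = 2)
  seg <- data.frame(chrom = "chr1", start = c(10e6, 50e6),
                    end = c(15e6, 55e6))
  tg <- plant_roh(ind, segments = seg)
  expect_equal(tg$froh_truth, 0.10)
  expect_equal(tg$planted_segments[bed_cols], seg, ignore_attr = TRUE)
})

test_that("no heterozygote survives inside any planted tract", {
  ch <- small_chain(seed = 77, target_froh = 0.2)
  tg <- ch$truth
  for (k in seq_len(nrow(tg$planted_segments))) {
    s <- tg$planted_segments[k, ]
    inside <- tg$sites$chrom == s$chrom &
      tg$sites$pos > s$start & tg$sites$pos <= s$end
    for (g in tg$gt[inside]) expect_true(g %in% c(0L, 2L))
  }
})

test_that("out-of-range planting requests error", {
  panel <- simulate_panel(panel_config(n_haplotypes = 10,
                                       chrom_lengths = c(chr1 = 1e6),
                                       site_density = 1e-4, seed = 1))
  ind <- sample_individual(panel, seed = 1)
  expect_error(plant_roh(ind, target_froh = 1.5), "F_ROH")
  expect_error(plant_roh(ind, segments = data.frame(chrom = "chr1",
                                                    start = 5e5, end = 2e6)),
               "bounds")
})

test_that("error-free corruption reproduces the truth", {
  ch <- small_chain(seed = 11)
  model <- corruption_model(err_hom_ref = 0, err_het = 0, err_hom_alt = 0,
                            coverage = 1, seed = 4)
  obs <- corrupt_genotypes(ch$truth, model)
  expect_identical(obs$gt[, 1], ch$truth$gt)
  expect_equal(n_sites(obs), length(ch$truth$gt))
})

test_that("corruption preserves site and sample counts", {
  ch <- small_chain(seed = 12)
  expect_equal(n_sites(ch$imputed), length(ch$truth$gt))
  expect_equal(n_samples(ch$imputed), 1L)
})

test_that("realized het flip rate is within 3 binomial SDs of the model", {
  m <- 120000
  truth <- raw_truth(rep(1L, m))
  p <- 0.05
  model <- corruption_model(err_het = p, maf_error_multiplier = 1,
                            jitter_shape = Inf, coverage = 1, seed = 21)
  obs <- corrupt_genotypes(truth, model)
  flipped <- mean(obs$gt[, 1] != 1L)
  expect_lt(abs(flipped - p), 3 * sqrt(p * (1 - p) / m))
})

test_that("low-INFO sites carry higher planted error than high-INFO sites", {
  ch <- small_chain(seed = 31, chrom_lengths = c(chr1 = 50e6))
  p_err <- attr(ch$imputed, "planted_error_prob")
  info <- ch$imputed$sites$info
  expect_gt(mean(p_err[info < 0.8]), mean(p_err[info >= 0.8]))
})

test_that("corruption is deterministic given the model seed", {
  ch <- small_chain(seed = 41)
  model <- corruption_model(seed = 99)
  expect_identical(corrupt_genotypes(ch$truth, model),
                   corrupt_genotypes(ch$truth, model))
})

test_that("pseudohaploid calls are haploid-coded and reproducible", {
  ch <- small_chain(seed = 51)
  ph <- pseudohaploid_table(ch$truth, missing_rate = 0.3, seed = 8)
  expect_true(all(ph$gt[, 1] %in% c(0L, 2L, NA)))
  expect_identical(ph, pseudohaploid_table(ch$truth, missing_rate = 0.3,
                                           seed = 8))
  # at a truly heterozygous site either allele may be drawn
  het <- ch$truth$gt == 1L & !is.na(ph$gt[, 1])
  expect_true(all(c(0L, 2L) %in% ph$gt[het, 1]))
})
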