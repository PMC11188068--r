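test_that("window tiling keeps the final partial window at true width", {
  win <- tile_windows(c(chr1 = 1.2e6, chr2 = 5e5), 5e5)
  expect_equal(nrow(win), 4)
  expect_equal(win$end[3] - win$start[3], 2e5)
  expect_equal(sum(win$end - win$start), 1.7e6)
})

test_that("prevalence matches a manual overlap table", {
  cl <- c(chr1 = 2e6)
  segs <- data.frame(
    chrom = "chr1",
    start = c(0, 490000, 1500000),
    end = c(200000, 510000, 1600000),
    sample = c("a1", "a1", "a2"))
  cohorts <- c(a1 = "anc", a2 = "anc", m1 = "mod")
  tr <- window_prevalence(segs, cohorts, cl, 5e5)
  # windows: [0,5e5) both a1 segs; [5e5,1e6) a1 tail; [1e6,1.5e6) none;
  # [1.5e6,2e6) a2
  expect_equal(tr$prev_anc, c(50, 50, 0, 50))
  expect_equal(tr$prev_mod, c(0, 0, 0, 0))
})

test_that("a fully ROH-covered sample scores 100% everywhere", {
  cl <- c(chr1 = 3e6)
  segs <- data.frame(chrom = "chr1", start = 0, end = 3e6, sample = "s")
  tr <- window_prevalence(segs, c(s = "anc"), cl)
  expect_true(all(tr$prev_anc == 100))
  none <- window_prevalence(segs[0, ], c(s = "anc"), cl)
  expect_true(all(none$prev_anc == 0))
})

test_that("depth outliers and empty windows are excluded with reasons", {
  cl <- c(chr1 = 5e6)
  tr <- window_prevalence(data.frame(chrom = "chr1", start = 0, end = 1e6,
                                     sample = "s"), c(s = "anc"), cl)
  depth <- rep(10, nrow(tr))
  tr1 <- exclude_outlier_windows(tr, depth)
  expect_false(any(tr1$excluded))  # constant depth: no exclusions
  depth[3] <- 100
  sites <- rep(10L, nrow(tr)); sites[5] <- 0L
  tr2 <- exclude_outlier_windows(tr, depth, sites)
  expect_equal(which(tr2$excluded), c(3L, 5L))
  expect_equal(tr2$exclude_reason[c(3, 5)], c("depth", "no_sites"))
  expect_true(is.na(tr2$prev_anc[3]))
  # retained + excluded = total tiling
  expect_equal(sum(tr2$excluded) + sum(!tr2$excluded), nrow(tr))
})

test_that("deserts require strictly <5% in both cohorts", {
  cl <- c(chr1 = 1.5e6)
  samples <- c(sprintf("a%02d", 1:20), sprintf("m%02d", 1:25))
  cohorts <- setNames(c(rep("anc", 20), rep("mod", 25)), samples)
  # window 1: 1/20 ancient = 5% exactly; window 2: 0/20 & 1/25 = 4%;
  # window 3: clean desert
  segs <- data.frame(chrom = "chr1",
                     start = c(0, 5.5e5),
                     end = c(1e5, 6.5e5),
                     sample = c("a01", "m01"))
  tr <- window_prevalence(segs, cohorts, cl, 5e5)
  d <- detect_deserts(tr, "anc", "mod")
  expect_equal(d$start, c(5e5, 1e6))  # window 1 excluded: exactly 5%
  # boundary case in the modern cohort too
  d10 <- detect_deserts(tr, "anc", "mod", threshold = 4)
  expect_equal(d10$start, 1e6)
  expect_error(detect_deserts(tr, "anc", "missing"), "prevalence")
})

test_that("desert count is monotone nonincreasing in the threshold", {
  set.seed(50)
  cl <- c(chr1 = 20e6)
  samples <- sprintf("s%02d", 1:30)
  cohorts <- setNames(rep(c("anc", "mod"), 15), samples)
  segs <- do.call(rbind, lapply(samples, function(s) {
    d <- random_segments(4, 8e5, 20e6)
    d$sample <- s
    d
  }))
  tr <- window_prevalence(segs, cohorts, cl)
  counts <- vapply(c(2, 5, 10, 20, 50),
                   function(th) nrow(detect_deserts(tr, "anc", "mod", th)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

# 10 genes, gene 1-5 candidates (overlap the desert window), a category
# holding genes 1 and 2 -> hypergeometric p = C(5,2)/C(10,2) = 10/45.
enrichment_toy <- function() {
  cl <- c(chr1 = 10e6)
  tr <- window_prevalence(data.frame(chrom = "chr1", start = 0, end = 1e5,
                                     sample = "x")[0, ],
                          c(x = "anc"), cl, 5e5)
  tr$excluded <- FALSE
  deserts <- data.frame(chrom = "chr1", start = 0, end = 4.5e6)
  genes <- data.frame(chrom = "chr1",
                      start = seq(0, 9e6, 1e6) + 1e5,
                      end = seq(0, 9e6, 1e6) + 3e5,
                      gene = sprintf("G%02d", 1:10))
  list(track = tr, deserts = deserts, genes = genes)
}

test_that("hypergeometric p matches the closed form on the 10-gene toy", {
  toy <- enrichment_toy()
  g2c <- data.frame(gene = c("G01", "G02"), category = "CAT1")
  out <- desert_enrichment(toy$track, toy$deserts, toy$genes, g2c,
                           n_permutations = 50, seed = 3)
  expect_equal(out$n_background_genes, 2)
  expect_equal(out$n_candidate_genes, 2)
  expect_equal(out$p, 10 / 45, tolerance = 1e-12)
})

test_that("a category with p = 1 has FWER = 1", {
  toy <- enrichment_toy()
  g2c <- data.frame(gene = c("G09", "G10"), category = "COLD")
  out <- desert_enrichment(toy$track, toy$deserts, toy$genes, g2c,
                           n_permutations = 50, seed = 3)
  expect_equal(out$p, 1)
  expect_equal(out$fwer, 1)
})

test_that("FWER is nondecreasing in observed p within one run", {
  toy <- enrichment_toy()
  g2c <- rbind(data.frame(gene = c("G01", "G02"), category = "HOT"),
               data.frame(gene = c("G01", "G08"), category = "WARM"),
               data.frame(gene = c("G09", "G10"), category = "COLD"))
  out <- desert_enrichment(toy$track, toy$deserts, toy$genes, g2c,
                           n_permutations = 200, seed = 5)
  expect_true(all(diff(out$fwer) >= 0))  # out is sorted by p
})

test_that("categories with no background gene are skipped with a warning", {
  toy <- enrichment_toy()
  g2c <- rbind(data.frame(gene = c("G01", "G02"), category = "OK"),
               data.frame(gene = "ABSENT", category = "GONE"))
  expect_warning(
    out <- desert_enrichment(toy$track, toy$deserts, toy$genes, g2c,
                             n_permutations = 20, seed = 1),
    "background")
  expect_equal(out$category, "OK")
})

test_that("enrichment is exactly reproducible under a fixed seed", {
  toy <- enrichment_toy()
  set.seed(77)
  g2c <- data.frame(gene = sample(toy$genes$gene, 12, replace = TRUE),
                    category = rep(c("C1", "C2", "C3"), each = 4))
  a <- desert_enrichment(toy$track, toy$deserts, toy$genes, g2c,
                         n_permutations = 100, seed = 11)
  b <- desert_enrichment(toy$track, toy$deserts, toy$genes, g2c,
                         n_permutations = 100, seed = 11)
  expect_identical(a, b)
})

test_that("genes overlapping only excluded windows leave the background", {
  toy <- enrichment_toy()
  toy$track$excluded[toy$track$start >= 5e6] <- TRUE
  g2c <- data.frame(gene = sprintf("G%02d", 1:10), category = "ALL")
  out <- desert_enrichment(toy$track, toy$deserts, toy$genes, g2c,
                           n_permutations = 20, seed = 2)
  expect_equal(out$n_background_genes, 5)  # genes 6-10 dropped
})
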