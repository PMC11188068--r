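# Synthetic genotype data with planted autozygosity.
#
# The generator builds a haplotype reference panel by mosaic copying from
# founder haplotypes, samples diploid individuals from the panel allele
# frequencies under Hardy-Weinberg (sites independent; linkage realism is
# an explicit non-goal), plants runs of homozygosity by duplicating one
# haplotype across a tract, and produces an "imputed-like" corrupted copy
# whose per-site INFO score is a monotone map of the planted error
# probability.

#' Configuration for the synthetic haplotype panel
#'
#' @param n_haplotypes number of haplotypes in the panel (>= 1).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param site_density expected segregating sites per bp (e.g. `1e-4` for
#'   one SNP per 10 kb).
#' @param n_founders number of founder haplotypes the remaining haplotypes
#'   are copied from. One founder and zero mutation gives a monomorphic
#'   panel.
#' @param mosaic_switch_rate per-bp probability that a copying haplotype
#'   switches template.
#' @param mutation_rate per-site flip probability applied on copy.
#' @param founder_af_beta shape parameters of the Beta distribution the
#'   founder allele frequencies are drawn from (U-shaped by default, so the
#'   panel has many rare variants).
#' @param seed integer seed.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(n_haplotypes = 100,
                         chrom_lengths = c(chr1 = 50e6),
                         site_density = 1e-4,
                         n_founders = 8,
                         mosaic_switch_rate = 1e-6,
                         mutation_rate = 1e-3,
                         founder_af_beta = c(0.4, 0.4),
                         seed = 1L) {
  if (n_haplotypes < 1) stop_contract("need at least one haplotype")
  if (any(chrom_lengths <= 0)) stop_contract("chromosome lengths must be > 0")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  rates <- c(site_density, mosaic_switch_rate, mutation_rate)
  if (any(rates < 0) || any(c(mosaic_switch_rate, mutation_rate) > 1))
    stop_contract("rates must lie in [0, 1]")
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 chrom_lengths = chrom_lengths,
                 site_density = site_density,
                 n_founders = as.integer(n_founders),
                 mosaic_switch_rate = mosaic_switch_rate,
                 mutation_rate = mutation_rate,
                 founder_af_beta = founder_af_beta,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Simulate a haplotype reference panel
#'
#' Founder haplotypes are drawn per site from Beta-distributed allele
#' frequencies; every further haplotype is a mosaic copy of the founders
#' (template switches occur at rate `mosaic_switch_rate` per bp) with
#' per-site mutations. Per-site alternative allele frequency is the mean
#' across haplotypes. Ref/alt nucleotides are assigned uniformly at random
#' so transition/transversion filters are exercisable.
#'
#' @param cfg a [panel_config()].
#' @return an object of class `haplotype_panel`: a list with `sites`
#'   (data.frame chrom/pos/ref/alt/af), `haplotypes` (0/1 matrix, sites x
#'   haplotypes) and `chrom_lengths`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(derive_seed(cfg$seed, "panel"), {
    sites_l <- list(); haps_l <- list()
    for (ch in names(cfg$chrom_lengths)) {
      L <- cfg$chrom_lengths[[ch]]
      m <- round(L * cfg$site_density)
      if (m < 1) next
      pos <- sort(sample.int(L, m))
      nt <- c("A", "C", "G", "T")
      ref <- sample(nt, m, replace = TRUE)
      alt <- vapply(ref, function(r) sample(nt[nt != r], 1), character(1))
      f <- min(cfg$n_founders, cfg$n_haplotypes)
      p0 <- rbeta(m, cfg$founder_af_beta[1], cfg$founder_af_beta[2])
      H <- matrix(0L, nrow = m, ncol = cfg$n_haplotypes)
      for (j in seq_len(f)) H[, j] <- rbinom(m, 1L, p0)
      if (cfg$n_haplotypes > f) {
        gap <- c(pos[1], diff(pos))
        p_switch <- 1 - (1 - cfg$mosaic_switch_rate)^gap
        for (j in (f + 1L):cfg$n_haplotypes) {
          switches <- runif(m) < p_switch
          switches[1] <- TRUE
          tmpl_id <- sample.int(f, sum(switches), replace = TRUE)
          tmpl <- tmpl_id[cumsum(switches)]
          h <- H[cbind(seq_len(m), tmpl)]
          if (cfg$mutation_rate > 0) {
            mut <- runif(m) < cfg$mutation_rate
            h[mut] <- 1L - h[mut]
          }
          H[, j] <- h
        }
      }
      sites_l[[ch]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                                  af = rowMeans(H), stringsAsFactors = FALSE)
      haps_l[[ch]] <- H
    }
    if (!length(sites_l)) stop_contract("configuration yields zero sites")
    sites <- do.call(rbind, sites_l)
    rownames(sites) <- NULL
    structure(list(sites = sites, haplotypes = do.call(rbind, haps_l),
                   chrom_lengths = cfg$chrom_lengths),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d sites x %d haplotypes, %d chromosome(s)\n",
              nrow(x$sites), ncol(x$haplotypes),
              length(x$chrom_lengths)))
  invisible(x)
}

#' Sample a diploid individual from panel allele frequencies
#'
#' Two haplotypes are drawn per site under Hardy-Weinberg equilibrium at
#' the panel allele frequency (sites independent). The pair of haplotypes
#' is retained so that [plant_roh()] can duplicate one of them across
#' autozygous tracts.
#'
#' @param panel a `haplotype_panel`.
#' @param seed integer seed.
#' @return an object of class `individual`: list with `sites`, `hap1`,
#'   `hap2` (0/1 vectors) and `chrom_lengths`.
#' @export
sample_individual <- function(panel, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  with_seed(derive_seed(seed, "individual"), {
    p <- panel$sites$af
    structure(list(sites = panel$sites,
                   hap1 = rbinom(length(p), 1L, p),
                   hap2 = rbinom(length(p), 1L, p),
                   chrom_lengths = panel$chrom_lengths),
              class = "individual")
  })
}

#' Plant runs of homozygosity in an individual
#'
#' Inside each planted tract one haplotype is duplicated over the other,
#' so every overlapping site becomes homozygous (dose 0 or 2); sites
#' outside the tracts are untouched. Tracts can be given explicitly or
#' drawn to reach a target genome fraction `target_froh` with a mix of
#' short and long segments.
#'
#' @param ind an [sample_individual()] result.
#' @param segments optional BED-like data.frame (chrom, start, end; 0-based
#'   half-open) of tracts to plant. Merged before planting.
#' @param target_froh optional target fraction of the genome inside planted
#'   tracts (alternative to `segments`).
#' @param length_range_short,length_range_long bp ranges that short and
#'   long tract lengths are drawn from when `target_froh` is used. The
#'   short/long split mirrors the 1.6 Mb boundary used downstream.
#' @param prop_long proportion of drawn tracts that are long.
#' @param forbidden optional BED-like data.frame of regions that drawn
#'   tracts must not touch (used to plant shared ROH-free deserts). A
#'   200 kb margin is kept around each forbidden region so that caller
#'   boundary effects cannot leak called ROH into it.
#' @param seed integer seed.
#' @return an object of class `truth_genome`: list with `sites`, `gt`
#'   (dose vector), `hap1`, `hap2`, `planted_segments`, `froh_truth` and
#'   `chrom_lengths`.
#' @export
plant_roh <- function(ind, segments = NULL, target_froh = NULL,
                      length_range_short = c(0.6e6, 1.6e6),
                      length_range_long = c(1.6e6, 4e6),
                      prop_long = 0.5, forbidden = NULL, seed = 1L) {
  stopifnot(inherits(ind, "individual"))
  genome_length <- sum(ind$chrom_lengths)
  if (!is.null(target_froh)) {
    if (target_froh < 0 || target_froh > 1)
      stop_contract("target F_ROH must lie in [0, 1]")
    segments <- with_seed(derive_seed(seed, "plant"), {
      draw_tracts(ind$chrom_lengths, target_froh,
                  length_range_short, length_range_long, prop_long,
                  forbidden = forbidden)
    })
  }
  segments <- merge_segments(check_segments(segments, "planted segments"))
  if (nrow(segments)) {
    cl <- ind$chrom_lengths[segments$chrom]
    if (any(is.na(cl)) || any(segments$end > cl) || any(segments$start < 0))
      stop_contract("planted segments fall outside chromosome bounds")
  }
  hap1 <- ind$hap1; hap2 <- ind$hap2
  for (k in seq_len(nrow(segments))) {
    inside <- ind$sites$chrom == segments$chrom[k] &
      ind$sites$pos > segments$start[k] & ind$sites$pos <= segments$end[k]
    hap2[inside] <- hap1[inside]
  }
  structure(list(sites = ind$sites, gt = hap1 + hap2,
                 hap1 = hap1, hap2 = hap2,
                 planted_segments = segments,
                 froh_truth = total_segment_length(segments) / genome_length,
                 chrom_lengths = ind$chrom_lengths),
            class = "truth_genome")
}

# Draw non-overlapping tracts totalling target*genome on one or more
# chromosomes; the last tract is trimmed so the total is hit exactly.
draw_tracts <- function(chrom_lengths, target, range_short, range_long,
                        prop_long, forbidden = NULL) {
  want <- target * sum(chrom_lengths)
  if (want == 0) return(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), stringsAsFactors = FALSE))
  placed <- 0; tries <- 0
  existing <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  if (!is.null(forbidden)) {
    forbidden <- check_segments(forbidden)[, c("chrom", "start", "end")]
    forbidden$start <- pmax(0, forbidden$start - 2e5)
    forbidden$end <- forbidden$end + 2e5
  }
  while (placed < want && tries < 10000) {
    tries <- tries + 1
    long <- runif(1) < prop_long
    r <- if (long) range_long else range_short
    len <- runif(1, r[1], r[2])
    len <- min(len, want - placed + r[1])  # avoid overshoot below min length
    ch <- sample(names(chrom_lengths), 1,
                 prob = chrom_lengths / sum(chrom_lengths))
    if (len >= chrom_lengths[[ch]]) next
    s <- floor(runif(1, 0, chrom_lengths[[ch]] - len))
    cand <- data.frame(chrom = ch, start = s, end = s + ceiling(len),
                       stringsAsFactors = FALSE)
    blockers <- rbind(existing, forbidden)
    ov <- blockers$chrom == ch & blockers$start < cand$end &
      blockers$end > cand$start
    if (any(ov)) next
    if (placed + (cand$end - cand$start) > want)
      cand$end <- cand$start + (want - placed)
    if (cand$end - cand$start < 1) break
    existing <- rbind(existing, cand)
    placed <- placed + (cand$end - cand$start)
  }
  existing
}

#' Imputation-like corruption model
#'
#' Describes how an observed low-coverage imputed callset is derived from
#' the truth: per-genotype-class flip probabilities (`err_hom_ref`,
#' `err_het`, `err_hom_alt`), a multiplier inflating errors at rare
#' variants (below `maf_threshold`), per-site error jitter, and the
#' monotone map from planted per-site error to the emitted INFO score
#' `INFO = clamp(1 - info_scale * site_error_factor, 0, 1)`. Because the
#' map is monotone, filtering on INFO provably enriches accuracy in the
#' synthetic world. Depth is Poisson around `coverage`.
#'
#' @param coverage mean read depth (x).
#' @param err_hom_ref,err_het,err_hom_alt per-class flip probabilities.
#' @param maf_error_multiplier factor applied to errors at sites with
#'   folded MAF below `maf_threshold`.
#' @param maf_threshold folded-MAF boundary for the multiplier.
#' @param jitter_shape shape of the unit-mean Gamma jitter applied to the
#'   per-site error factor (larger = less site-to-site variation;
#'   `Inf` disables the jitter entirely).
#' @param info_scale slope of the error-to-INFO map.
#' @param seed integer seed.
#' @return an object of class `corruption_model`.
#' @export
corruption_model <- function(coverage = 0.5,
                             err_hom_ref = 0.02, err_het = 0.05,
                             err_hom_alt = 0.10,
                             maf_error_multiplier = 3,
                             maf_threshold = 0.05,
                             jitter_shape = 4,
                             info_scale = 2.5,
                             seed = 1L) {
  probs <- c(err_hom_ref, err_het, err_hom_alt)
  if (any(probs < 0 | probs > 1))
    stop_contract("error probabilities must lie in [0, 1]")
  if (coverage < 0) stop_contract("coverage must be >= 0")
  structure(list(coverage = coverage, err_hom_ref = err_hom_ref,
                 err_het = err_het, err_hom_alt = err_hom_alt,
                 maf_error_multiplier = maf_error_multiplier,
                 maf_threshold = maf_threshold,
                 jitter_shape = jitter_shape, info_scale = info_scale,
                 seed = as.integer(seed)),
            class = "corruption_model")
}

#' Corrupt truth genotypes into an imputed-like callset
#'
#' Each genotype flips with its class error probability times the site
#' error factor (MAF multiplier x Gamma jitter), clamped to 1. Hom-ref
#' errors go mostly to het; het errors split evenly between the two
#' homozygous classes; hom-alt errors go mostly to het. INFO is the
#' monotone map of the site error factor; depth is Poisson around the
#' model coverage; alt-read counts are binomial around the observed dose.
#'
#' @param truth a `truth_genome` (or an `individual`).
#' @param model a [corruption_model()].
#' @param sample_name name of the emitted sample column.
#' @return a [genotype_table()] with one sample, carrying `af`, `info`,
#'   `dp`, `ad_alt` annotations and an attribute `planted_error_prob`
#'   (per-site realized flip probability).
#' @export
corrupt_genotypes <- function(truth, model, sample_name = "imputed") {
  stopifnot(inherits(model, "corruption_model"))
  gt <- if (inherits(truth, "truth_genome")) truth$gt else truth$hap1 + truth$hap2
  sites <- truth$sites
  m <- length(gt)
  with_seed(derive_seed(model$seed, "corrupt"), {
    maf <- pmin(sites$af, 1 - sites$af)
    factor_site <- if (is.finite(model$jitter_shape))
      rgamma(m, shape = model$jitter_shape, rate = model$jitter_shape)
    else rep(1, m)
    factor_site <- factor_site *
      ifelse(maf < model$maf_threshold, model$maf_error_multiplier, 1)
    class_err <- c(model$err_hom_ref, model$err_het, model$err_hom_alt)[gt + 1L]
    p_err <- clamp01(class_err * factor_site)
    flip <- runif(m) < p_err
    obs <- gt
    if (any(flip)) {
      u <- runif(sum(flip))
      from <- gt[flip]
      to <- integer(sum(flip))
      to[from == 0L] <- ifelse(u[from == 0L] < 0.9, 1L, 2L)
      to[from == 1L] <- ifelse(u[from == 1L] < 0.5, 0L, 2L)
      to[from == 2L] <- ifelse(u[from == 2L] < 0.9, 1L, 0L)
      obs[flip] <- to
    }
    info <- clamp01(1 - model$info_scale * class_err * factor_site)
    dp <- rpois(m, model$coverage)
    af_read <- c(0.01, 0.5, 0.99)[obs + 1L]
    ad_alt <- rbinom(m, dp, af_read)
    sites$info <- info
    tab <- genotype_table(sites, matrix(obs, ncol = 1),
                          dp = matrix(dp, ncol = 1),
                          ad_alt = matrix(ad_alt, ncol = 1),
                          samples = sample_name,
                          chrom_lengths = truth$chrom_lengths)
    attr(tab, "planted_error_prob") <- p_err
    tab
  })
}

#' Truth genotype table for a synthetic individual
#'
#' Packages a `truth_genome` as a high-coverage validation-style callset:
#' Poisson depth around `coverage`, allele-balance consistent read counts,
#' and a genotype posterior near 1 (drawn from a Beta concentrated at
#' `prob_mean`).
#'
#' @param truth a `truth_genome`.
#' @param coverage mean truth depth (default 20x, a high-coverage genome).
#' @param prob_mean mean genotype posterior emitted.
#' @param sample_name sample column name.
#' @param seed integer seed.
#' @return a [genotype_table()] with one sample.
#' @export
truth_table <- function(truth, coverage = 20, prob_mean = 0.99,
                        sample_name = "truth", seed = 1L) {
  stopifnot(inherits(truth, "truth_genome"))
  m <- length(truth$gt)
  with_seed(derive_seed(seed, "truth_table"), {
    dp <- rpois(m, coverage)
    af_read <- c(0.01, 0.5, 0.99)[truth$gt + 1L]
    ad_alt <- rbinom(m, dp, af_read)
    prob <- rbeta(m, prob_mean * 200, (1 - prob_mean) * 200)
    genotype_table(truth$sites, matrix(truth$gt, ncol = 1),
                   dp = matrix(dp, ncol = 1),
                   ad_alt = matrix(ad_alt, ncol = 1),
                   prob = matrix(prob, ncol = 1),
                   samples = sample_name,
                   chrom_lengths = truth$chrom_lengths)
  })
}

#' Pseudohaploid copy of a truth genome
#'
#' Emulates single-read sampling: at each site one of the two true
#' alleles is chosen at random and reported as a homozygous diploid call
#' (dose 0 or 2), the standard representation of pseudohaploid calls.
#'
#' @param truth a `truth_genome`.
#' @param missing_rate fraction of sites reported missing.
#' @param sample_name sample column name.
#' @param seed integer seed.
#' @return a [genotype_table()] with one sample.
#' @export
pseudohaploid_table <- function(truth, missing_rate = 0.2,
                                sample_name = "pseudohaploid", seed = 1L) {
  stopifnot(inherits(truth, "truth_genome"))
  m <- length(truth$gt)
  with_seed(derive_seed(seed, "pseudohaploid"), {
    pick <- runif(m) < 0.5
    allele <- ifelse(pick, truth$hap1, truth$hap2)
    dose <- 2L * as.integer(allele)
    dose[runif(m) < missing_rate] <- NA_integer_
    genotype_table(truth$sites, matrix(dose, ncol = 1),
                   samples = sample_name,
                   chrom_lengths = truth$chrom_lengths)
  })
}
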