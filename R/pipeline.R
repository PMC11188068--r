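# End-to-end orchestration: a benchmark mode (synthesize -> corrupt ->
# filter -> score concordance / ROH accuracy / PC distance across
# coverage levels) and an analysis mode (call ROH -> F_ROH cohort
# statistics -> windowed landscape -> deserts -> enrichment), with a JSON
# manifest recording seed, configuration hash and output checksums.

#' Default mapping from emulated coverage to corruption parameters
#'
#' Benchmark-mode "downsampling" is emulated by scaling the corruption
#' model rather than resampling reads: lower coverage means higher
#' per-class genotype error. The default table spans the six coverage
#' levels conventionally benchmarked (0.05x-2x), with hom-ref and het
#' errors below 5\% from 0.5x upwards and hom-alt errors roughly twice
#' the het errors, the ordering seen in real imputed ancient genomes.
#'
#' @return data.frame with columns `coverage`, `err_hom_ref`, `err_het`,
#'   `err_hom_alt`.
#' @export
default_coverage_error_table <- function() {
  data.frame(
    coverage    = c(0.05, 0.1, 0.2, 0.5, 1, 2),
    err_hom_ref = c(0.10, 0.06, 0.030, 0.015, 0.008, 0.005),
    err_het     = c(0.30, 0.20, 0.100, 0.045, 0.025, 0.015),
    err_hom_alt = c(0.45, 0.32, 0.200, 0.090, 0.060, 0.040))
}

#' Pipeline run configuration
#'
#' @param mode `"benchmark"` or `"analysis"`.
#' @param outdir output directory (created if absent).
#' @param seed top-level seed; every stage derives its own sub-stream.
#' @param coverage_levels coverages to emulate in benchmark mode.
#' @param coverage_error_table coverage -> error mapping, see
#'   [default_coverage_error_table()].
#' @param chrom_lengths named vector of chromosome lengths for the
#'   synthetic genome.
#' @param site_density synthetic sites per bp.
#' @param n_reference number of reference individuals for the PC space
#'   and, in analysis mode, the modern cohort size.
#' @param target_froh planted F_ROH of the benchmark truth genome.
#' @param n_per_cohort analysis mode: samples per cohort.
#' @param cohort_froh analysis mode: named planted F_ROH per cohort.
#' @param desert_region optional BED-like one-row data.frame kept free of
#'   ROH in every analysis-mode sample (a planted desert).
#' @param filter a [filter_spec()].
#' @param roh a [roh_params()].
#' @param n_permutations permutations for the enrichment FWER.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("benchmark", "analysis"), outdir, seed = 1L,
                       coverage_levels = c(0.05, 0.1, 0.2, 0.5, 1, 2),
                       coverage_error_table = default_coverage_error_table(),
                       chrom_lengths = c(chr1 = 20e6, chr2 = 20e6),
                       site_density = 2e-4,
                       n_reference = 20,
                       target_froh = 0.1,
                       n_per_cohort = 10,
                       cohort_froh = c(ancient = 0.05, modern = 0.2),
                       desert_region = NULL,
                       filter = filter_spec(),
                       roh = roh_params(),
                       n_permutations = 200) {
  mode <- match.arg(mode)
  if (any(coverage_levels <= 0)) stop_contract("coverage levels must be > 0")
  structure(list(mode = mode, outdir = outdir, seed = as.integer(seed),
                 coverage_levels = coverage_levels,
                 coverage_error_table = coverage_error_table,
                 chrom_lengths = chrom_lengths,
                 site_density = site_density,
                 n_reference = n_reference, target_froh = target_froh,
                 n_per_cohort = n_per_cohort, cohort_froh = cohort_froh,
                 desert_region = desert_region,
                 filter = filter, roh = roh,
                 n_permutations = n_permutations),
            class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(cfg)[setdiff(names(cfg), "outdir")], file = tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, files) {
  manifest <- list(
    package = "paleoroh",
    version = as.character(utils::packageVersion("paleoroh")),
    mode = cfg$mode, seed = cfg$seed, config_md5 = config_hash(cfg),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

interpolate_errors <- function(tab, coverage) {
  f <- function(col) stats::approx(tab$coverage, tab[[col]], xout = coverage,
                                   rule = 2)$y
  list(err_hom_ref = f("err_hom_ref"), err_het = f("err_het"),
       err_hom_alt = f("err_hom_alt"))
}

#' Run the benchmark pipeline
#'
#' Synthesizes a truth genome with planted ROH, then for each coverage
#' level produces an imputed-like corrupted callset and a pseudohaploid
#' callset and scores them against the truth: per-class error rates and
#' NRD, r-squared by MAF bin under INFO cutoffs, ROH-overlap accuracy of
#' the called versus planted segments, and weighted PC distances to the
#' truth projection. Writes `concordance.tsv`, `r2_by_maf.tsv`,
#' `roh_accuracy.tsv`, `pc_distance.tsv` and `manifest.json` to
#' `cfg$outdir`.
#'
#' @param cfg a [run_config()] with `mode = "benchmark"`.
#' @return invisibly, a list of the emitted tables.
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"), cfg$mode == "benchmark")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(panel_config(
    n_haplotypes = 2 * cfg$n_reference,
    chrom_lengths = cfg$chrom_lengths,
    site_density = cfg$site_density,
    seed = derive_seed(cfg$seed, "bench_panel")))
  truth <- plant_roh(sample_individual(panel,
                                       seed = derive_seed(cfg$seed, "bench_ind")),
                     target_froh = cfg$target_froh,
                     seed = derive_seed(cfg$seed, "bench_plant"))
  tt <- truth_table(truth, seed = derive_seed(cfg$seed, "bench_truth"))
  ref_tab <- reference_table(panel, cfg$n_reference,
                             seed = derive_seed(cfg$seed, "bench_ref"))
  space <- fit_pca(ref_tab, k = min(10, cfg$n_reference - 1))
  truth_coords <- project_sample(tt, space)
  genome_length <- sum(cfg$chrom_lengths)
  conc <- list(); r2 <- list(); acc <- list(); pcd <- list()
  for (cov in cfg$coverage_levels) {
    er <- interpolate_errors(cfg$coverage_error_table, cov)
    model <- corruption_model(coverage = cov,
                              err_hom_ref = er$err_hom_ref,
                              err_het = er$err_het,
                              err_hom_alt = er$err_hom_alt,
                              seed = derive_seed(cfg$seed,
                                                 paste0("corrupt", cov)))
    imp <- corrupt_genotypes(truth, model)
    rates <- error_rates(tally_confusion(tt, imp))
    conc[[length(conc) + 1L]] <- data.frame(
      coverage = cov, err_hom_ref = rates$err_hom_ref,
      err_het = rates$err_het, err_hom_alt = rates$err_hom_alt,
      nrd = rates$nrd)
    r2_tab <- r2_by_maf_bin(tt, imp)
    r2_tab$coverage <- cov
    r2[[length(r2) + 1L]] <- r2_tab
    imp_f <- post_imputation_filter(imp, cfg$filter)
    called <- call_roh(roh_track(imp_f), cfg$roh)
    lc <- length_confusion(called[, c("chrom", "start", "end")],
                           truth$planted_segments, genome_length)
    met <- overlap_metrics(lc)
    seg_met <- overlap_metrics(
      segment_confusion(called[, c("chrom", "start", "end")],
                        truth$planted_segments))
    acc[[length(acc) + 1L]] <- data.frame(
      coverage = cov, f1_length = met$f1, nmcc_length = met$nmcc,
      sensitivity = met$sensitivity, specificity = met$specificity,
      fdr = met$fdr, f1_segment = seg_met$f1)
    # no read covers a site with probability exp(-coverage) under Poisson
    ph <- pseudohaploid_table(truth, missing_rate = exp(-cov),
                              seed = derive_seed(cfg$seed,
                                                 paste0("pseudo", cov)))
    pcd[[length(pcd) + 1L]] <- data.frame(
      coverage = cov,
      dist_imputed = weighted_pc_distance(project_sample(imp, space),
                                          truth_coords, space,
                                          k = ncol(space$loadings)),
      dist_pseudohaploid = weighted_pc_distance(project_sample(ph, space),
                                                truth_coords, space,
                                                k = ncol(space$loadings)))
  }
  tables <- list(concordance = do.call(rbind, conc),
                 r2_by_maf = do.call(rbind, r2),
                 roh_accuracy = do.call(rbind, acc),
                 pc_distance = do.call(rbind, pcd))
  files <- c(write_tsv(tables$concordance,
                       file.path(cfg$outdir, "concordance.tsv")),
             write_tsv(tables$r2_by_maf,
                       file.path(cfg$outdir, "r2_by_maf.tsv")),
             write_tsv(tables$roh_accuracy,
                       file.path(cfg$outdir, "roh_accuracy.tsv")),
             write_tsv(tables$pc_distance,
                       file.path(cfg$outdir, "pc_distance.tsv")))
  write_manifest(cfg, files)
  invisible(tables)
}

# Diploid reference table drawn from panel allele frequencies.
reference_table <- function(panel, n, seed = 1L) {
  with_seed(derive_seed(seed, "reference"), {
    p <- panel$sites$af
    gt <- vapply(seq_len(n), function(j)
      rbinom(length(p), 2L, p), integer(length(p)))
    genotype_table(panel$sites, gt,
                   samples = sprintf("REF%02d", seq_len(n)),
                   chrom_lengths = panel$chrom_lengths)
  })
}

#' Run the analysis pipeline
#'
#' Synthesizes per-cohort samples with planted inbreeding levels, calls
#' ROH per sample, and emits the downstream population analyses: F_ROH
#' summaries, pairwise rank-sum tests, the windowed ROH-prevalence
#' track, desert windows, and gene-category enrichment over a synthetic
#' annotation. Writes `froh.tsv`, `rank_sum.tsv`, `window_track.tsv`,
#' `deserts.bed`, `enrichment.tsv` and `manifest.json`.
#'
#' @param cfg a [run_config()] with `mode = "analysis"`.
#' @return invisibly, a list of the emitted tables.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"), cfg$mode == "analysis")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(panel_config(
    n_haplotypes = 2 * cfg$n_reference,
    chrom_lengths = cfg$chrom_lengths,
    site_density = cfg$site_density,
    seed = derive_seed(cfg$seed, "an_panel")))
  genome_length <- sum(cfg$chrom_lengths)
  segs <- list(); meta <- list(); cohorts <- character()
  for (co in names(cfg$cohort_froh)) {
    for (i in seq_len(cfg$n_per_cohort)) {
      sid <- sprintf("%s%02d", co, i)
      sseed <- derive_seed(cfg$seed, paste0("an_", sid))
      truth <- plant_roh(sample_individual(panel, seed = sseed),
                         target_froh = cfg$cohort_froh[[co]],
                         forbidden = cfg$desert_region, seed = sseed)
      called <- call_roh(
        data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
                   gt = truth$gt, stringsAsFactors = FALSE),
        cfg$roh)
      if (nrow(called)) {
        called$sample <- sid
        segs[[length(segs) + 1L]] <- called[, c("chrom", "start", "end",
                                                "sample")]
      }
      meta[[length(meta) + 1L]] <- data.frame(
        sample = sid, cohort = co,
        age_bp = if (co == names(cfg$cohort_froh)[1]) 5000 + 100 * i else 0,
        stringsAsFactors = FALSE)
      cohorts[sid] <- co
    }
  }
  seg_all <- do.call(rbind, segs)
  metadata <- do.call(rbind, meta)
  fs <- froh_summary(seg_all, genome_length, metadata)
  rs <- pairwise_rank_sum(fs)
  track <- window_prevalence(seg_all, cohorts, cfg$chrom_lengths)
  depth <- with_seed(derive_seed(cfg$seed, "an_depth"),
                     rnorm(nrow(track), mean = 10, sd = 0.5))
  nsite <- count_sites_per_window(track, panel$sites)
  track <- exclude_outlier_windows(track, depth, nsite)
  deserts <- detect_deserts(track, names(cfg$cohort_froh)[1],
                            names(cfg$cohort_froh)[2])
  ann <- synthetic_annotation(cfg$chrom_lengths,
                              seed = derive_seed(cfg$seed, "an_genes"))
  enr <- desert_enrichment(track, deserts, ann$genes, ann$gene2cat,
                           n_permutations = cfg$n_permutations,
                           seed = derive_seed(cfg$seed, "an_enrich"))
  tables <- list(froh = fs, rank_sum = rs, window_track = track,
                 deserts = deserts[, c("chrom", "start", "end")],
                 enrichment = enr)
  files <- c(write_tsv(fs, file.path(cfg$outdir, "froh.tsv")),
             write_tsv(rs, file.path(cfg$outdir, "rank_sum.tsv")),
             write_tsv(as.data.frame(track),
                       file.path(cfg$outdir, "window_track.tsv")),
             write_tsv(tables$deserts, file.path(cfg$outdir, "deserts.bed")),
             write_tsv(enr, file.path(cfg$outdir, "enrichment.tsv")))
  write_manifest(cfg, files)
  invisible(tables)
}

count_sites_per_window <- function(track, sites) {
  wgr <- segments_to_granges(as.data.frame(track)[, c("chrom", "start", "end")])
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  GenomicRanges::countOverlaps(wgr, sgr)
}

#' Random gene annotation and category assignment
#'
#' A stand-in (synthetic) gene annotation for the enrichment stage:
#' gene spans dropped uniformly on the genome and a random gene-to-
#' category map.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param n_genes number of genes.
#' @param n_categories number of categories.
#' @param genes_per_category genes drawn per category (with replacement
#'   across categories, so genes may carry several annotations).
#' @param length_range gene length range in bp.
#' @param seed integer seed.
#' @return list with `genes` (BED-like with `gene`) and `gene2cat`.
#' @export
synthetic_annotation <- function(chrom_lengths, n_genes = 400,
                                 n_categories = 25,
                                 genes_per_category = 15,
                                 length_range = c(5e3, 2e5), seed = 1L) {
  with_seed(derive_seed(seed, "annotation"), {
    ch <- sample(names(chrom_lengths), n_genes, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    len <- runif(n_genes, length_range[1], length_range[2])
    start <- floor(runif(n_genes, 0, chrom_lengths[ch] - len))
    genes <- data.frame(chrom = ch, start = start,
                        end = start + ceiling(len),
                        gene = sprintf("G%04d", seq_len(n_genes)),
                        stringsAsFactors = FALSE)
    gene2cat <- do.call(rbind, lapply(seq_len(n_categories), function(k)
      data.frame(gene = sample(genes$gene, genes_per_category),
                 category = sprintf("CAT%03d", k),
                 stringsAsFactors = FALSE)))
    list(genes = genes, gene2cat = gene2cat)
  })
}
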