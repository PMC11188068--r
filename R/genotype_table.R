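#' Per-site, per-sample diploid genotype table
#'
#' The central container of the package: biallelic SNP genotypes coded as
#' alt-allele dose (0, 1, 2; `NA` = missing), together with per-site
#' annotations (panel allele frequency `af`, imputation-quality `info`,
#' optional site `qual`) and per-sample, per-site depth (`dp`), alt-allele
#' read depth (`ad_alt`) and genotype posterior (`prob`).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `af`, `info`, `qual`. Positions must be strictly
#'   increasing within each chromosome.
#' @param gt integer matrix, sites x samples, values in `{0,1,2,NA}`.
#' @param dp,ad_alt,prob optional numeric matrices with the same shape as
#'   `gt`: read depth, alt-allele read depth, genotype posterior.
#' @param samples character vector of sample names (defaults to
#'   `colnames(gt)` or `S1..Sk`).
#' @param chrom_lengths optional named numeric vector of chromosome sizes
#'   in bp.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, gt, dp = NULL, ad_alt = NULL, prob = NULL,
                           samples = NULL, chrom_lengths = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (nrow(sites) != n)
    stop_contract("sites (%d rows) and gt (%d rows) disagree", nrow(sites), n)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stop_contract("sites must have chrom/pos/ref/alt columns")
  bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
  if (any(bad)) stop_contract("genotype doses must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop_contract("positions not strictly increasing on %s", ch)
  }
  samples <- samples %||% colnames(gt) %||% paste0("S", seq_len(ncol(gt)))
  colnames(gt) <- samples
  shape_ok <- function(m) is.null(m) || all(dim(m) == dim(gt))
  if (!shape_ok(dp) || !shape_ok(ad_alt) || !shape_ok(prob))
    stop_contract("dp/ad_alt/prob must match the shape of gt")
  structure(list(sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 gt = gt, dp = dp, ad_alt = ad_alt, prob = prob,
                 samples = samples, chrom_lengths = chrom_lengths),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), n_samples(x), length(unique(x$sites$chrom))))
  ann <- c(if (!is.null(x$sites$af)) "AF", if (!is.null(x$sites$info)) "INFO",
           if (!is.null(x$dp)) "DP", if (!is.null(x$ad_alt)) "AD",
           if (!is.null(x$prob)) "PP")
  if (length(ann)) cat("annotations:", paste(ann, collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites / samples in a genotype table
#' @param x a `genotype_table`.
#' @return integer count.
#' @export
n_sites <- function(x) nrow(x$gt)

#' @rdname n_sites
#' @export
n_samples <- function(x) ncol(x$gt)

#' Subset a genotype table by site
#'
#' @param x a `genotype_table`.
#' @param i logical or integer site index.
#' @param ... unused.
#' @return a `genotype_table` restricted to the selected sites.
#' @export
`[.genotype_table` <- function(x, i, ...) {
  sub <- function(m) if (is.null(m)) NULL else m[i, , drop = FALSE]
  genotype_table(x$sites[i, , drop = FALSE], sub(x$gt), dp = sub(x$dp),
                 ad_alt = sub(x$ad_alt), prob = sub(x$prob),
                 samples = x$samples, chrom_lengths = x$chrom_lengths)
}

#' Folded minor allele frequency of each site
#' @param x a `genotype_table` with an `af` annotation.
#' @return numeric vector, `min(af, 1 - af)` per site.
#' @export
site_maf <- function(x) {
  if (is.null(x$sites$af)) stop_contract("table carries no AF annotation")
  pmin(x$sites$af, 1 - x$sites$af)
}

dose_to_gt_string <- function(d) {
  out <- c("0/0", "0/1", "1/1")[d + 1L]
  out[is.na(d)] <- "./."
  out
}

gt_string_to_dose <- function(s) {
  s <- gsub("\\|", "/", s)
  d <- rep(NA_integer_, length(s))
  d[s == "0/0"] <- 0L
  d[s %in% c("0/1", "1/0")] <- 1L
  d[s == "1/1"] <- 2L
  d
}

#' Write a genotype table as VCF v4.2
#'
#' Emits a plain-text VCF with `FORMAT GT:DP:AD` (plus `PP` when genotype
#' posteriors are present) and site-level `AF` and `INFO` annotations, the
#' layout produced by low-coverage imputation tools. Chromosome lengths,
#' when known, are written as `##contig` lines.
#'
#' @param x a `genotype_table`.
#' @param path output file path (plain text, not compressed).
#' @return `path`, invisibly.
#' @seealso [read_callset()]
#' @export
write_callset <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  s <- x$sites
  hdr <- c("##fileformat=VCFv4.2", "##source=paleoroh")
  if (!is.null(x$chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(x$chrom_lengths),
                          as.integer(x$chrom_lengths)))
  hdr <- c(hdr,
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Panel alternative allele frequency\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  has_pp <- !is.null(x$prob)
  if (has_pp)
    hdr <- c(hdr, "##FORMAT=<ID=PP,Number=1,Type=Float,Description=\"Genotype posterior\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", x$samples),
                      collapse = "\t"))
  info_col <- rep(".", n_sites(x))
  have_af <- !is.null(s$af)
  have_info <- !is.null(s$info)
  if (have_af || have_info) {
    parts <- cbind(if (have_af) sprintf("AF=%.6f", s$af) else NULL,
                   if (have_info) sprintf("INFO=%.6f", s$info) else NULL)
    info_col <- apply(parts, 1, paste, collapse = ";")
  }
  qual_col <- if (is.null(s$qual)) rep(".", n_sites(x)) else
    ifelse(is.na(s$qual), ".", sprintf("%g", s$qual))
  fmt <- paste(c("GT", if (!is.null(x$dp)) "DP", if (!is.null(x$ad_alt)) "AD",
                 if (has_pp) "PP"), collapse = ":")
  cells <- dose_to_gt_string(x$gt)
  dim(cells) <- dim(x$gt)
  if (!is.null(x$dp)) {
    dpc <- ifelse(is.na(x$dp), ".", format(x$dp, trim = TRUE, scientific = FALSE))
    cells <- matrix(paste(cells, dpc, sep = ":"), nrow = nrow(cells))
  }
  if (!is.null(x$ad_alt)) {
    ref_d <- pmax(x$dp - x$ad_alt, 0)
    adc <- ifelse(is.na(x$ad_alt), ".",
                  paste0(format(ref_d, trim = TRUE), ",", format(x$ad_alt, trim = TRUE)))
    cells <- matrix(paste(cells, adc, sep = ":"), nrow = nrow(cells))
  }
  if (has_pp) {
    ppc <- ifelse(is.na(x$prob), ".", sprintf("%.4f", x$prob))
    cells <- matrix(paste(cells, ppc, sep = ":"), nrow = nrow(cells))
  }
  body <- paste(s$chrom, as.integer(s$pos), ".", s$ref, s$alt, qual_col, "PASS",
                info_col, fmt, sep = "\t")
  if (ncol(cells) > 0)
    body <- paste(body, apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF callset into a genotype table
#'
#' Parses a biallelic SNP VCF (as written by [write_callset()] or by an
#' imputation pipeline) via `VariantAnnotation::readVcf` and converts it to
#' a [genotype_table()].
#'
#' @param path VCF file path.
#' @return a `genotype_table`.
#' @export
read_callset <- function(path) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e)
      stop_contract("failed to parse VCF '%s': %s", path, conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  if (is(alt, "List") || is.list(alt)) {
    if (any(lengths(alt) != 1L))
      stop_contract("multi-allelic records in '%s'; only biallelic SNPs supported", path)
    alt <- as.character(unlist(alt))
  } else alt <- as.character(alt)
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt, stringsAsFactors = FALSE)
  info <- VariantAnnotation::info(vcf)
  if ("AF" %in% names(info)) {
    af <- info[["AF"]]
    if (is(af, "List") || is.list(af)) af <- as.numeric(unlist(af))
    sites$af <- as.numeric(af)
  }
  if ("INFO" %in% names(info)) {
    sc <- info[["INFO"]]
    if (is(sc, "List") || is.list(sc)) sc <- as.numeric(unlist(sc))
    sites$info <- as.numeric(sc)
  }
  q <- VariantAnnotation::qual(vcf)
  if (!all(is.na(q))) sites$qual <- as.numeric(q)
  g <- VariantAnnotation::geno(vcf)
  gt <- gt_string_to_dose(g$GT)
  dim(gt) <- dim(g$GT)
  dp <- if ("DP" %in% names(g)) {
    m <- g$DP; storage.mode(m) <- "integer"; m
  } else NULL
  ad_alt <- if ("AD" %in% names(g)) {
    ad <- g$AD
    m <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
    if (is.list(ad)) {
      m[] <- vapply(ad, function(v)
        if (length(v) >= 2) as.integer(v[2]) else NA_integer_, integer(1))
    } else if (length(dim(ad)) == 3L) {
      m[] <- as.integer(ad[, , 2])
    }
    m
  } else NULL
  prob <- if ("PP" %in% names(g)) {
    m <- g$PP; storage.mode(m) <- "numeric"; m
  } else NULL
  cl <- GenomeInfoDb::seqlengths(vcf)
  cl <- cl[!is.na(cl)]
  genotype_table(sites, gt, dp = dp, ad_alt = ad_alt, prob = prob,
                 samples = colnames(g$GT),
                 chrom_lengths = if (length(cl)) cl else NULL)
}

#' Read a two-column chrom-sizes table
#' @param path TSV with columns chromosome name and length in bp.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "length"),
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d$length), d$chrom)
}
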