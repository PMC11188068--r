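# Principal-component space from a reference genotype matrix, with
# least-squares projection of sparse samples and weighted PC distances.

#' Fit a PC space from a reference genotype table
#'
#' Standardizes the sites-x-samples dose matrix the way smartpca does:
#' each site is centred by its mean dose and scaled by `sqrt(p*(1-p))`,
#' where `p` is the shrunken allele frequency `(count+1)/(2n+2)` (the
#' shrinkage avoids division by zero at near-fixed sites). Missing
#' reference genotypes are mean-imputed before fitting; monomorphic
#' sites are dropped. The decomposition is computed by SVD of the
#' standardized matrix; reference coordinates are the PC scores.
#'
#' @param reference a multi-sample [genotype_table()] (>= 2 samples).
#' @param k number of components to retain (reduced with a warning when
#'   fewer are available).
#' @return an object of class `pc_space`: list with `sites` (keys),
#'   `center`, `scale`, `loadings` (sites x K, orthonormal),
#'   `eigenvalues` (length K, nonincreasing), `coords` (samples x K).
#' @export
fit_pca <- function(reference, k = 10) {
  stopifnot(inherits(reference, "genotype_table"))
  ns <- n_samples(reference)
  if (ns < 2) stop_contract("PCA needs at least two reference samples")
  G <- reference$gt  # sites x samples
  n_called <- rowSums(!is.na(G))
  count_alt <- rowSums(G, na.rm = TRUE)
  p <- (count_alt + 1) / (2 * n_called + 2)
  mu <- count_alt / n_called
  poly <- apply(G, 1, function(g) length(unique(g[!is.na(g)])) > 1)
  keep <- n_called > 0 & poly
  G <- G[keep, , drop = FALSE]
  mu <- mu[keep]; p <- p[keep]
  sc <- sqrt(p * (1 - p))
  X <- (G - mu) / sc
  X[is.na(X)] <- 0
  kk <- min(k, ns - 1, nrow(G))
  if (kk < k)
    warning(sprintf("only %d components available; k reduced from %d",
                    kk, k), call. = FALSE)
  sv <- svd(t(X), nu = kk, nv = kk)
  coords <- sv$u %*% diag(sv$d[seq_len(kk)], kk, kk)
  rownames(coords) <- reference$samples
  structure(list(site_key = paste(reference$sites$chrom[keep],
                                  reference$sites$pos[keep], sep = ":"),
                 center = mu, scale = sc,
                 loadings = sv$v,
                 eigenvalues = sv$d[seq_len(kk)]^2 / (ns - 1),
                 coords = coords),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("pc_space: %d sites, %d reference samples, %d components\n",
              length(x$site_key), nrow(x$coords), ncol(x$loadings)))
  invisible(x)
}

#' Project a (possibly sparse) sample onto a PC space
#'
#' Least-squares fit of the standardized non-missing doses onto the site
#' loadings restricted to those sites (the lsproject-style projection
#' used for low-coverage and pseudohaploid samples). Projecting a
#' complete reference sample reproduces its fitted coordinates.
#'
#' @param sample a single-sample [genotype_table()], or a named numeric
#'   dose vector keyed like `chrom:pos`.
#' @param space a [fit_pca()] result.
#' @return numeric coordinate vector of length K.
#' @export
project_sample <- function(sample, space) {
  stopifnot(inherits(space, "pc_space"))
  if (inherits(sample, "genotype_table")) {
    if (n_samples(sample) != 1L)
      stop_contract("project one sample at a time")
    g <- stats::setNames(as.numeric(sample$gt[, 1]),
                         paste(sample$sites$chrom, sample$sites$pos, sep = ":"))
  } else g <- sample
  idx <- match(space$site_key, names(g))
  obs <- which(!is.na(idx) & !is.na(g[idx]))
  if (!length(obs))
    stop_contract("no non-missing sites shared with the PC space")
  z <- (g[idx[obs]] - space$center[obs]) / space$scale[obs]
  V <- space$loadings[obs, , drop = FALSE]
  as.numeric(solve(crossprod(V), crossprod(V, z)))
}

#' Sum of weighted PC distances between two coordinate vectors
#'
#' `sum_k w_k * |a_k - b_k|` over the first `k` components, with weights
#' `w_k = eigenvalue_k / sum(eigenvalues[1:k])`, so displacement along a
#' component counts in proportion to the variance that component
#' explains. Symmetric, and zero iff the two coordinate vectors agree on
#' the first `k` components.
#'
#' @param a,b numeric coordinate vectors covering at least `k` components.
#' @param space the [fit_pca()] result providing the eigenvalues.
#' @param k number of leading components (default 10).
#' @return a scalar distance.
#' @export
weighted_pc_distance <- function(a, b, space, k = 10) {
  stopifnot(inherits(space, "pc_space"))
  if (k > length(space$eigenvalues) || k > length(a) || k > length(b))
    stop_contract("k exceeds the available components")
  ev <- space$eigenvalues[seq_len(k)]
  w <- ev / sum(ev)
  sum(w * abs(a[seq_len(k)] - b[seq_len(k)]))
}
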