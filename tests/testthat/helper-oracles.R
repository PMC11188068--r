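# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with plain loops, sharing no code with the
# implementations they check.

# Sliding-window ROH caller: direct enumeration of every window and rule.
oracle_call_roh <- function(pos, gt, params) {
  n <- length(pos)
  w <- params$window_snp
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_snps = integer(), length_kb = numeric())
  if (n < w) return(empty)
  W <- n - w + 1L
  pass <- logical(W)
  for (j in seq_len(W)) {
    win <- gt[j:(j + w - 1L)]
    n_het <- sum(win == 1L, na.rm = TRUE)
    n_mis <- sum(is.na(win))
    pass[j] <- n_het <= params$window_het && n_mis <= params$window_missing
  }
  eligible <- logical(n)
  for (i in seq_len(n)) {
    covering <- seq_len(W)
    covering <- covering[covering <= i & covering + w - 1L >= i]
    eligible[i] <- sum(pass[covering]) / length(covering) >=
      params$window_threshold
  }
  segs <- empty
  run <- integer()
  flush <- function(run, segs) {
    if (!length(run)) return(segs)
    span <- pos[run[length(run)]] - (pos[run[1]] - 1)
    if (length(run) >= params$min_snp && span >= params$min_kb * 1000 &&
        (span / 1000) / length(run) <= params$max_density_kb_per_snp)
      segs <- rbind(segs, data.frame(start = pos[run[1]] - 1,
                                     end = pos[run[length(run)]],
                                     n_snps = length(run),
                                     length_kb = span / 1000))
    segs
  }
  for (i in seq_len(n)) {
    if (eligible[i]) {
      if (length(run) &&
          (run[length(run)] != i - 1L ||
           pos[i] - pos[run[length(run)]] > params$max_gap_kb * 1000)) {
        segs <- flush(run, segs)
        run <- integer()
      }
      run <- c(run, i)
    } else {
      segs <- flush(run, segs)
      run <- integer()
    }
  }
  flush(run, segs)
}

# Pearson r^2 from the textbook sum formulas.
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# Mann-Whitney U by direct pairwise comparison counting.
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Exact two-sided rank-sum p by enumerating labelings of the raw values.
oracle_rank_sum_p <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  na <- length(a)
  obs <- oracle_u(a, b)
  center <- na * length(b) / 2
  combs <- combn(n, na)
  hits <- 0
  for (j in seq_len(ncol(combs))) {
    ga <- vals[combs[, j]]
    gb <- vals[-combs[, j]]
    if (abs(oracle_u(ga, gb) - center) >= abs(obs - center) - 1e-9)
      hits <- hits + 1
  }
  hits / ncol(combs)
}

# Four-cell MCC evaluated directly.
oracle_mcc <- function(tp, fp, fn, tn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

# Allele frequency by explicit counting over haplotypes.
oracle_af <- function(H) {
  out <- numeric(nrow(H))
  for (i in seq_len(nrow(H))) {
    acc <- 0
    for (j in seq_len(ncol(H))) acc <- acc + H[i, j]
    out[i] <- acc / ncol(H)
  }
  out
}
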