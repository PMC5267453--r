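# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact two-sided rank-sum p-value by enumeration of all C(n, n1)
# assignments of the pooled (mid)ranks to group 1.
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  sums <- combn(n, n1, function(idx) sum(r[idx]))
  lo <- mean(sums <= obs + 1e-9)
  hi <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Explicit 2x2-inverse least-squares oracle for the purity design:
# adjugate inverse, explicit residual split, sandwich variance.
oracle_fit <- function(z, W, n0, n1) {
  a <- sum(W[, 1]^2)
  b <- sum(W[, 1] * W[, 2])
  d <- sum(W[, 2]^2)
  inv <- matrix(c(d, -b, -b, a), 2, 2) / (a * d - b * b)
  H <- inv %*% t(W)
  beta <- drop(H %*% z)
  resid <- z - drop(W %*% beta)
  s2 <- sum(resid[seq_len(n0)]^2) / (n0 - 2)
  s2p <- sum(resid[n0 + seq_len(n1)]^2) / (n1 - 2)
  H1 <- H[, seq_len(n0), drop = FALSE]
  H2 <- H[, n0 + seq_len(n1), drop = FALSE]
  V <- s2 * H1 %*% t(H1) + s2p * H2 %*% t(H2)
  list(beta = beta, var_beta = V, sigma2 = s2, sigma2_prime = s2p)
}

# Rank-based AUC of 'score' against logical 'truth' (Mann-Whitney form).
auc_rank <- function(score, truth) {
  r <- rank(score)
  (mean(r[truth]) - (sum(truth) + 1) / 2) / sum(!truth)
}

# Purity-ignoring pooled-variance two-sample t-test on transformed
# values; the comparator for power-dominance checks.
naive_ttest_p <- function(Z, groups) {
  tum <- Z[, groups$tumor_ids, drop = FALSE]
  ctl <- Z[, groups$normal_ids, drop = FALSE]
  n1 <- ncol(tum)
  n0 <- ncol(ctl)
  s2p <- ((n1 - 1) * apply(tum, 1, var) +
            (n0 - 1) * apply(ctl, 1, var)) / (n0 + n1 - 2)
  tt <- (rowMeans(tum) - rowMeans(ctl)) / sqrt(s2p * (1 / n0 + 1 / n1))
  2 * pt(abs(tt), df = n0 + n1 - 2, lower.tail = FALSE)
}

# Sensitivity at the largest cutoff whose empirical false-discovery
# proportion stays below q, walking down the p-value ranking.
sens_at_fdp <- function(p, truth, q = 0.10) {
  ord <- order(p)
  fdp <- cumsum(!truth[ord]) / seq_along(ord)
  ok <- which(fdp <= q)
  if (!length(ok)) return(0)
  sum(truth[ord][seq_len(max(ok))]) / sum(truth)
}

# Small beta matrix written to a temp file; returns the path.
write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
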