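#' Arcsine transform of beta values
#'
#' Variance-stabilizing map f(x) = arcsin(2x - 1) from \[0, 1\] to
#' \[-pi/2, pi/2\]. Transformed beta values are approximately Gaussian,
#' and because the map is close to linear over most of its range, a
#' mixture that is a weighted average on the beta scale stays close to a
#' weighted average on the transformed scale - which is what lets purity
#' enter the linear model as a multiplicative design factor.
#'
#' @param beta Numeric vector or matrix of beta values in \[0, 1\]
#'   (`NA` allowed).
#' @return Object of the same shape with values arcsin(2v - 1).
#' @export
arcsine_transform <- function(beta) {
  v <- unclass(beta)
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("beta values must lie in [0, 1]")
  asin(2 * v - 1)
}

# Inverse of the arcsine transform, with clamping of the argument.
inverse_arcsine <- function(t) {
  t <- pmin(pmax(t, -pi / 2), pi / 2)
  (sin(t) + 1) / 2
}

#' Build the purity design matrix
#'
#' The response stacks normal samples first, then tumor samples. The
#' design has an intercept column and a purity column that is 0 for
#' normals and the sample's purity for tumors, encoding the mixture
#' identity: an observed tumor methylome with purity lambda carries
#' lambda times the cancer-normal difference. With all purities equal to
#' 1 the design reduces to the ordinary two-group indicator design.
#'
#' @param groups A [sample_groups()] with at least 3 samples per group.
#' @param purity Named purity vector or [estimate_purity()] result
#'   covering every tumor sample.
#' @return List with `W` (n0+n1 x 2 design), `sample_order` (normals then
#'   tumors), `n0`, `n1`, `lambda`.
#' @export
build_design <- function(groups, purity) {
  stopifnot(inherits(groups, "sample_groups"))
  lam <- as_purity_vector(purity)
  miss <- setdiff(groups$tumor_ids, names(lam))
  if (length(miss))
    stop("no purity for tumor sample(s): ", paste(miss, collapse = ", "))
  n0 <- length(groups$normal_ids)
  n1 <- length(groups$tumor_ids)
  lam <- unname(lam[groups$tumor_ids])
  W <- cbind(intercept = 1, purity = c(rep(0, n0), lam))
  if (qr(W)$rank < 2)
    stop("design matrix is rank deficient (needs normals or dispersed ",
         "purities)")
  list(W = W,
       sample_order = c(groups$normal_ids, groups$tumor_ids),
       n0 = n0, n1 = n1, lambda = lam)
}

# Shared least-squares core: given the site-by-sample matrix Z (rows =
# sites, columns in design order) and a design list, returns per-site
# estimates and group residual variances. Vectorized across sites.
ls_core <- function(Z, design) {
  W <- design$W; n0 <- design$n0; n1 <- design$n1
  H <- solve(crossprod(W), t(W))          # 2 x (n0+n1), H = (W'W)^-1 W'
  B <- Z %*% t(H)                         # sites x 2: (m_hat, mu_hat)
  E <- Z - B %*% t(W)                     # residuals
  idx_n <- seq_len(n0)
  idx_t <- n0 + seq_len(n1)
  sigma2 <- rowSums(E[, idx_n, drop = FALSE]^2) / (n0 - 2)
  sigma2_prime <- rowSums(E[, idx_t, drop = FALSE]^2) / (n1 - 2)
  # var(beta_hat)[2,2] = s2 * sum(H[2, normals]^2) +
  #                      s2' * sum(H[2, tumors]^2)
  list(m_hat = B[, 1], mu_hat = B[, 2],
       sigma2 = sigma2, sigma2_prime = sigma2_prime,
       c_normal = sum(H[2, idx_n]^2), c_tumor = sum(H[2, idx_t]^2),
       H = H)
}

#' Fit the purity-aware linear model at one CpG site
#'
#' Solves the normal equation beta_hat = (W'W)^-1 W' Z for the site's
#' stacked transformed values Z, giving the baseline mean m_hat and the
#' cancer-normal difference mu_hat on the arcsine scale. Residual
#' variances are estimated separately in the two groups (denominators
#' n0 - 2 and n1 - 2), and the variance of beta_hat is assembled from the
#' block-diagonal var(Z) = diag(sigma2 I_n0, sigma2' I_n1) as
#' H1 Sigma H1' + H2 Sigma' H2'.
#'
#' @param z Numeric vector of arcsine-transformed values in design order
#'   (normals first, then tumors).
#' @param design A design list from [build_design()].
#' @return List with `m_hat`, `mu_hat`, `se_mu`, `sigma2`,
#'   `sigma2_prime`, `var_beta` (2 x 2), `df`.
#' @export
fit_site <- function(z, design) {
  n0 <- design$n0; n1 <- design$n1
  if (n0 <= 2 || n1 <= 2)
    stop("fit_site needs n0 > 2 and n1 > 2 (variance denominators ",
         "n0 - 2 and n1 - 2)")
  if (length(z) != n0 + n1)
    stop("length of 'z' must equal n0 + n1")
  if (anyNA(z)) stop("missing values are not allowed in 'z'")
  core <- ls_core(matrix(z, nrow = 1), design)
  H <- core$H
  idx_n <- seq_len(n0); idx_t <- n0 + seq_len(n1)
  H1 <- H[, idx_n, drop = FALSE]; H2 <- H[, idx_t, drop = FALSE]
  var_beta <- core$sigma2 * tcrossprod(H1) +
    core$sigma2_prime * tcrossprod(H2)
  dimnames(var_beta) <- NULL
  list(m_hat = unname(core$m_hat), mu_hat = unname(core$mu_hat),
       se_mu = sqrt(var_beta[2, 2]),
       sigma2 = unname(core$sigma2),
       sigma2_prime = unname(core$sigma2_prime),
       var_beta = var_beta, df = n0 + n1 - 2)
}

#' Shrink residual variances toward their geometric mean
#'
#' Linear shrinkage on the log scale: log sigma_tilde^2 =
#' (1 - w) log sigma_hat^2 + w g, where g is the mean log variance over
#' sites. The geometric mean of the vector is preserved for every w;
#' w = 0 returns the input and w = 1 collapses all variances to the
#' geometric mean. Zero variances are floored at machine epsilon before
#' taking logs (messaged).
#'
#' @param variances Numeric vector of per-site variance estimates.
#' @param weight Shrinkage weight in \[0, 1\] (default 0.2).
#' @return Numeric vector of shrunken variances.
#' @export
shrink_variances <- function(variances, weight = 0.2) {
  if (length(weight) != 1 || is.na(weight) || weight < 0 || weight > 1)
    stop("'weight' must be a single value in [0, 1]")
  v <- variances
  zero <- v <= 0
  if (any(zero)) {
    message(sum(zero), " zero variance(s) floored at machine epsilon")
    v[zero] <- .Machine$double.eps
  }
  lv <- log(v)
  exp((1 - weight) * lv + weight * mean(lv))
}

#' Wald test for the cancer-normal difference
#'
#' t = mu_hat / se(mu_hat), referred to a t distribution with
#' n0 + n1 - 2 degrees of freedom, two-sided. A zero standard error
#' (degenerate site) yields p = 1 when mu_hat = 0 and p = 0 otherwise,
#' with a warning.
#'
#' @param mu_hat Estimated difference (vectorized).
#' @param se_mu Standard error(s), recomputed from shrunken variances.
#' @param n0,n1 Group sizes.
#' @return List with `t_stat`, `p_value`, `df`.
#' @export
wald_test <- function(mu_hat, se_mu, n0, n1) {
  df <- n0 + n1 - 2
  t_stat <- mu_hat / se_mu
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  degen <- !is.na(se_mu) & se_mu == 0
  if (any(degen)) {
    warning(sum(degen), " site(s) with zero standard error; p set by ",
            "sign convention")
    null_mu <- abs(mu_hat[degen]) <= sqrt(.Machine$double.eps)
    t_stat[degen] <- ifelse(null_mu, 0, Inf * sign(mu_hat[degen]))
    p[degen] <- ifelse(null_mu, 1, 0)
  }
  list(t_stat = t_stat, p_value = p, df = df)
}

#' Purity-aware differential methylation calling (with normal controls)
#'
#' Per-site pipeline: arcsine transform, normal-equation fit of the
#' purity design ([build_design()]), separate residual-variance
#' estimation in the normal and tumor groups, geometric-mean variance
#' shrinkage within each group ([shrink_variances()]), Wald test on the
#' cancer-normal difference, and Benjamini-Hochberg FDR across all
#' tested sites. Sites with missing values among the used samples are
#' dropped (complete-case per site) and the count reported.
#'
#' @param beta A [beta_matrix()] with tumor and normal samples.
#' @param groups A [sample_groups()] with >= 3 samples per group.
#' @param purity Named purity vector or [estimate_purity()] result for
#'   the tumor samples.
#' @param shrink_weight Variance-shrinkage weight in \[0, 1\]
#'   (default 0.2).
#' @return A data frame of class `"dm_result"` with columns `site_id`,
#'   `m_hat`, `mu_hat`, `se`, `t`, `df`, `p`, `fdr`, `flag` (`"degenerate"`
#'   for zero-variance sites, otherwise `"ok"`).
#' @export
call_dm <- function(beta, groups, purity, shrink_weight = 0.2) {
  check_groups(beta, groups)
  design <- build_design(groups, purity)
  if (design$n0 <= 2 || design$n1 <= 2)
    stop("call_dm needs at least 3 normal and 3 tumor samples")
  sub <- drop_incomplete_sites(beta, design$sample_order,
                               context = "DM calling")
  if (!nrow(sub)) stop("no complete site to test")
  Z <- arcsine_transform(sub[, design$sample_order, drop = FALSE])
  core <- ls_core(Z, design)

  degen <- core$sigma2 <= .Machine$double.eps &
    core$sigma2_prime <= .Machine$double.eps
  s2 <- suppressMessages(shrink_variances(core$sigma2, shrink_weight))
  s2p <- suppressMessages(shrink_variances(core$sigma2_prime,
                                           shrink_weight))
  se <- sqrt(s2 * core$c_normal + s2p * core$c_tumor)
  se[degen] <- 0
  wt <- suppressWarnings(wald_test(core$mu_hat, se, design$n0, design$n1))
  if (any(degen))
    warning(sum(degen), " degenerate site(s) with zero residual ",
            "variance in both groups; flagged")

  out <- data.frame(site_id = rownames(sub),
                    m_hat = unname(core$m_hat),
                    mu_hat = unname(core$mu_hat),
                    se = se,
                    t = wt$t_stat,
                    df = wt$df,
                    p = wt$p_value,
                    fdr = stats::p.adjust(wt$p_value, method = "BH"),
                    flag = ifelse(degen, "degenerate", "ok"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n0") <- design$n0
  attr(out, "n1") <- design$n1
  attr(out, "shrink_weight") <- shrink_weight
  attr(out, "n_dropped") <- nrow(beta) - nrow(sub)
  class(out) <- c("dm_result", "data.frame")
  out
}

#' @export
print.dm_result <- function(x, ...) {
  if (is.null(x$fdr)) return(print.data.frame(x))
  cat("Purity-aware differential methylation:", nrow(x), "sites tested",
      "(", attr(x, "n0"), "normal,", attr(x, "n1"), "tumor )\n")
  cat("  FDR < 0.05:", sum(x$fdr < 0.05), "sites;  FDR < 0.01:",
      sum(x$fdr < 0.01), "sites\n")
  invisible(x)
}

#' @export
summary.dm_result <- function(object, fdr_cutoffs = c(0.01, 0.05, 0.1),
                              ...) {
  counts <- vapply(fdr_cutoffs, function(a) sum(object$fdr < a),
                   integer(1))
  res <- list(n_sites = nrow(object),
              n0 = attr(object, "n0"), n1 = attr(object, "n1"),
              shrink_weight = attr(object, "shrink_weight"),
              calls = data.frame(fdr_cutoff = fdr_cutoffs, n_dmc = counts),
              n_degenerate = sum(object$flag == "degenerate"))
  class(res) <- "summary.dm_result"
  res
}

#' @export
print.summary.dm_result <- function(x, ...) {
  cat("Purity-aware DM test:", x$n_sites, "sites,", x$n0, "normal vs",
      x$n1, "tumor samples (shrinkage weight ", x$shrink_weight, ")\n")
  print(x$calls, row.names = FALSE)
  if (x$n_degenerate)
    cat("  degenerate sites:", x$n_degenerate, "\n")
  invisible(x)
}
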