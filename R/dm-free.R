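#' Regress one site's methylation on tumor purity
#'
#' Simple linear regression of arcsine-transformed tumor methylation on
#' purity. Because the mixture signal at a differentially methylated
#' site varies with the fraction of tumor cells, the regression slope
#' estimates the cancer-normal difference mu on the transformed scale -
#' no normal samples required. The t statistic of the slope is
#' algebraically identical to the Pearson-correlation test statistic
#' r * sqrt((n - 2) / (1 - r^2)).
#'
#' @param y Numeric vector of transformed values for one site across
#'   tumor samples (length >= 4).
#' @param lambdas Numeric purity vector, same length and order as `y`,
#'   not all equal.
#' @return List with `mu_hat` (slope), `se_mu`, `t_stat`, `pearson_r`.
#' @export
regress_on_purity <- function(y, lambdas) {
  n <- length(y)
  if (n < 4) stop("need at least 4 tumor samples")
  if (length(lambdas) != n) stop("'y' and 'lambdas' lengths differ")
  if (anyNA(y) || anyNA(lambdas)) stop("missing values are not allowed")
  if (stats::sd(lambdas) == 0)
    stop("purity dispersion insufficient: all purities are equal")
  sxx <- sum((lambdas - mean(lambdas))^2)
  slope <- sum((lambdas - mean(lambdas)) * (y - mean(y))) / sxx
  if (stats::sd(y) == 0)
    return(list(mu_hat = 0, se_mu = 0, t_stat = 0, pearson_r = 0))
  resid <- y - mean(y) - slope * (lambdas - mean(lambdas))
  rss <- sum(resid^2)
  # an exact linear fit leaves only rounding residue; treat it as zero
  syy <- sum((y - mean(y))^2)
  if (rss <= 100 * .Machine$double.eps * syy) rss <- 0
  se <- sqrt(rss / (n - 2) / sxx)
  t_stat <- if (se > 0) slope / se else Inf * sign(slope)
  r <- stats::cor(y, lambdas)
  list(mu_hat = slope, se_mu = se, t_stat = t_stat, pearson_r = r)
}

#' Posterior probability that the effect size exceeds a threshold
#'
#' Plug-in posterior mu ~ Normal(mu_hat, se_mu^2):
#' Pr(|mu| > c) = Phi((-c - mu_hat)/se_mu) + 1 - Phi((c - mu_hat)/se_mu).
#' Ranking by this probability demotes sites whose test statistic is
#' large only because the standard error is tiny while the effect itself
#' is small. With c = 0 the probability is identically 1, so a c = 0
#' ranking falls back to ordering by |t| (equivalently |r|).
#'
#' @param mu_hat Estimated effect(s) on the arcsine scale (note: `c` is
#'   on this scale, not the beta scale).
#' @param se_mu Standard error(s), > 0.
#' @param c Effect-size threshold >= 0 (default 0.1).
#' @return Probability vector in \[0, 1\].
#' @export
posterior_prob <- function(mu_hat, se_mu, c = 0.1) {
  if (any(is.na(se_mu)) || any(se_mu <= 0))
    stop("'se_mu' must be positive")
  if (length(c) != 1 || is.na(c) || c < 0) stop("'c' must be >= 0")
  if (c == 0) return(rep(1, length(mu_hat)))  # exact boundary value
  pmin(stats::pnorm((-c - mu_hat) / se_mu) +
         stats::pnorm((c - mu_hat) / se_mu, lower.tail = FALSE), 1)
}

#' Control-free differential methylation calling
#'
#' Detects DMCs from tumor samples alone: each site's arcsine-transformed
#' values are regressed on purity ([regress_on_purity()]), the posterior
#' probability Pr(|mu| > c) is computed ([posterior_prob()]), and sites
#' are ranked by descending posterior probability with |t| as the
#' tie-break. The method needs a reasonably large cohort (a warning is
#' issued below 20 tumor samples) and purities dispersed enough for the
#' regression to be informative.
#'
#' @param beta A [beta_matrix()] containing the tumor samples.
#' @param tumor_ids Tumor sample ids (default: all columns of `beta`).
#' @param purity Named purity vector or [estimate_purity()] result.
#' @param c Effect-size threshold on the arcsine scale (default 0.1).
#' @param dispersion_floor Minimum sd of purities (default 0.05).
#' @param p_values If `TRUE`, add a two-sided t-based `p` column
#'   (df = n1 - 2). Off by default: the intended output is a ranking.
#' @return A data frame of class `"dm_free_result"` with columns
#'   `site_id`, `mu_hat`, `se`, `t`, `pearson_r`, `post_prob`, `rank`.
#' @export
call_dm_control_free <- function(beta, tumor_ids = colnames(beta),
                                 purity, c = 0.1,
                                 dispersion_floor = 0.05,
                                 p_values = FALSE) {
  tumor_ids <- as.character(tumor_ids)
  miss <- setdiff(tumor_ids, colnames(beta))
  if (length(miss))
    stop("sample id(s) not found in the beta matrix: ",
         paste(miss, collapse = ", "))
  n1 <- length(tumor_ids)
  if (n1 < 4) stop("control-free DM calling needs at least 4 tumor ",
                   "samples")
  if (n1 < 20)
    warning("control-free DM calling is recommended for cohorts of ",
            "more than 20 tumor samples (got ", n1, ")")
  lam <- as_purity_vector(purity)
  miss <- setdiff(tumor_ids, names(lam))
  if (length(miss))
    stop("no purity for tumor sample(s): ", paste(miss, collapse = ", "))
  lam <- unname(lam[tumor_ids])
  if (stats::sd(lam) < dispersion_floor)
    stop("purity dispersion insufficient: sd(purity) = ",
         format(stats::sd(lam), digits = 3), " < floor ",
         dispersion_floor)

  sub <- drop_incomplete_sites(beta, tumor_ids,
                               context = "control-free DM calling")
  if (!nrow(sub)) stop("no complete site to test")
  Y <- arcsine_transform(sub[, tumor_ids, drop = FALSE])

  # vectorized simple regression across sites
  lc <- lam - mean(lam)
  sxx <- sum(lc^2)
  ybar <- rowMeans(Y)
  slope <- (Y %*% lc) / sxx
  slope <- drop(slope)
  fitted_dev <- outer(slope, lc)
  rss <- rowSums((Y - ybar - fitted_dev)^2)
  syy <- rowSums((Y - ybar)^2)
  rss[rss <= 100 * .Machine$double.eps * syy] <- 0
  se <- sqrt(rss / (n1 - 2) / sxx)
  sy <- sqrt(rowSums((Y - ybar)^2))
  r <- ifelse(sy > 0, drop(Y %*% lc) / (sy * sqrt(sxx)), 0)
  t_stat <- ifelse(se > 0, slope / se,
                   ifelse(slope == 0, 0, Inf * sign(slope)))
  # zero-variance sites: define a null result, matching regress_on_purity
  constant_y <- sy == 0
  slope[constant_y] <- 0; t_stat[constant_y] <- 0

  post <- ifelse(se > 0,
                 posterior_prob(slope, pmax(se, .Machine$double.xmin),
                                c = c),
                 as.numeric(abs(slope) > c))
  ord <- order(-post, -abs(t_stat), rownames(sub))
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)

  out <- data.frame(site_id = rownames(sub),
                    mu_hat = slope, se = se, t = t_stat,
                    pearson_r = r, post_prob = post, rank = rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (p_values)
    out$p <- 2 * stats::pt(abs(out$t), df = n1 - 2, lower.tail = FALSE)
  attr(out, "n1") <- n1
  attr(out, "c") <- c
  class(out) <- c("dm_free_result", "data.frame")
  out
}

#' @export
print.dm_free_result <- function(x, ...) {
  if (is.null(x$rank) || is.null(x$post_prob))
    return(print.data.frame(x))
  cat("Control-free differential methylation:", nrow(x), "sites,",
      attr(x, "n1"), "tumor samples, effect threshold c =",
      attr(x, "c"), "\n")
  cat("  sites with Pr(|mu| > c) > 0.95:", sum(x$post_prob > 0.95), "\n")
  top <- x[order(x$rank), ][seq_len(min(5, nrow(x))), ]
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}
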