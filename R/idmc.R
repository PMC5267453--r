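#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided rank-sum test using the normal approximation with tie and
#' continuity corrections (the approximation is used uniformly; exact
#' enumeration is only meaningful at very small n). The statistic
#' returned is the Mann-Whitney U of `x` centred at its null mean, so
#' larger |statistic| means stronger separation.
#'
#' @param x Numeric values of group A (length >= 2).
#' @param y Numeric values of group B (length >= 1).
#' @return List with elements `statistic` (centred U) and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 1)
    stop("rank_sum_test needs at least 2 values in x and 1 in y")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n1 <- length(x); n2 <- length(y)
  if (length(unique(c(x, y))) == 1L) {
    message("all values tied across both groups; p set to 1")
    return(list(statistic = 0, p_value = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  )
  stat <- unname(wt$statistic) - n1 * n2 / 2
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = stat, p_value = min(p, 1))
}

#' Select informative differentially methylated CpGs (iDMCs)
#'
#' Screens CpG sites for use as purity markers: sites must have beta-value
#' variance above `var_min` in the tumor group, are tested tumor vs
#' control with the rank-sum test, and the `n_top` sites with smallest
#' p-values are retained. Each retained site is labelled `hyper` if its
#' mean tumor beta exceeds the mean control beta, else `hypo` (exact ties
#' count as hyper). Ties in p are broken by larger |statistic|, then by
#' site id, so the selection is deterministic.
#'
#' @param beta A [beta_matrix()] containing both groups.
#' @param groups A [sample_groups()] with >= 2 tumor and >= 2 control
#'   samples.
#' @param n_top Number of sites to keep (default 1000).
#' @param var_min Minimum tumor-group beta variance (default 0.005).
#' @return A data frame of class `"idmc_set"` with columns `site_id`,
#'   `direction`, `statistic`, `p_value`, `tumor_var`, `rank`.
#' @export
select_idmcs <- function(beta, groups, n_top = 1000, var_min = 0.005) {
  check_groups(beta, groups)
  if (length(groups$tumor_ids) < 2 || length(groups$normal_ids) < 2)
    stop("iDMC selection needs at least 2 tumor and 2 control samples")
  if (n_top < 1) stop("'n_top' must be >= 1")
  used <- c(groups$tumor_ids, groups$normal_ids)
  sub <- drop_incomplete_sites(beta, used, context = "iDMC selection")
  tum <- sub[, groups$tumor_ids, drop = FALSE]
  ctl <- sub[, groups$normal_ids, drop = FALSE]

  tumor_var <- apply(tum, 1, stats::var)
  keep <- tumor_var > var_min
  if (!any(keep))
    stop("no site passes the tumor-variance filter (> ", var_min, ")")
  if (sum(keep) < n_top)
    warning("only ", sum(keep), " site(s) pass the variance filter; ",
            "returning fewer than n_top = ", n_top)
  tum <- tum[keep, , drop = FALSE]
  ctl <- ctl[keep, , drop = FALSE]
  tumor_var <- tumor_var[keep]

  tests <- suppressMessages(
    lapply(seq_len(nrow(tum)),
           function(i) rank_sum_test(tum[i, ], ctl[i, ]))
  )
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  stat <- vapply(tests, `[[`, numeric(1), "statistic")
  if (all(p > 0.99))
    warning("no differential methylation signal between tumor and ",
            "control groups; iDMC set is arbitrary")

  ord <- order(p, -abs(stat), rownames(tum))
  ord <- ord[seq_len(min(n_top, length(ord)))]
  direction <- ifelse(rowMeans(tum[ord, , drop = FALSE]) >=
                        rowMeans(ctl[ord, , drop = FALSE]),
                      "hyper", "hypo")
  out <- data.frame(site_id = rownames(tum)[ord],
                    direction = direction,
                    statistic = stat[ord],
                    p_value = p[ord],
                    tumor_var = unname(tumor_var[ord]),
                    rank = seq_along(ord),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  as_idmc_set(out)
}

#' @export
print.idmc_set <- function(x, ...) {
  cat("iDMC set:", nrow(x), "sites (",
      sum(x$direction == "hyper"), "hyper,",
      sum(x$direction == "hypo"), "hypo )\n")
  if ("p_value" %in% colnames(x))
    cat("  p-value range: [", format(min(x$p_value), digits = 3), ", ",
        format(max(x$p_value), digits = 3), "]\n", sep = "")
  invisible(x)
}
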