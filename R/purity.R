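#' Direction-transform iDMC beta values for one tumor sample
#'
#' Hyper-methylated iDMCs keep their beta value; hypo-methylated iDMCs
#' are flipped to 1 - beta. The flip is applied by direction label alone,
#' regardless of the value itself, so a hypo site at beta 0.6 maps to
#' 0.4. After the transform, every iDMC reads out the fraction of the
#' tumor methylome present in the mixture.
#'
#' @param beta_column Named numeric vector of beta values for one tumor
#'   sample, indexed by site id.
#' @param idmc An `idmc_set` (from [select_idmcs()] or
#'   [read_idmc_list()]).
#' @return Numeric vector of transformed values, one per usable iDMC.
#' @export
transform_idmc_betas <- function(beta_column, idmc) {
  stopifnot(inherits(idmc, "idmc_set"))
  v <- beta_column[idmc$site_id]
  usable <- !is.na(v)
  n_drop <- sum(!usable)
  if (n_drop > 0)
    message(n_drop, " iDMC site(s) missing from the sample; dropped")
  if (n_drop > length(v) / 2)
    stop("more than 50% of iDMC sites are missing for this sample")
  v <- v[usable]
  dir <- idmc$direction[usable]
  if (any(v < 0 | v > 1)) stop("beta values must lie in [0, 1]")
  ifelse(dir == "hypo", 1 - v, v)
}

#' Mode of a Gaussian kernel density on \[0, 1\]
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth (floored at
#' `bw_floor` so degenerate point masses still yield a density),
#' evaluated on `n_grid` equispaced points over \[0, 1\]. The mode is the
#' grid point of globally maximal density; ties go to the smallest grid
#' point. If the density has more than one local maximum the count of
#' secondary peaks is messaged as a stability diagnostic.
#'
#' @param values Numeric vector in \[0, 1\], length >= 10.
#' @param bw_floor Minimum bandwidth (default 0.01).
#' @param n_grid Number of grid points (default 1001, i.e. resolution
#'   0.001).
#' @return List with `mode`, `peak_height` and `bandwidth`.
#' @export
density_mode <- function(values, bw_floor = 0.01, n_grid = 1001) {
  if (length(values) < 10)
    stop("too few values for density estimation (need >= 10, got ",
         length(values), ")")
  if (any(is.na(values))) stop("missing values are not allowed")
  # Silverman's rule of thumb; spelled out so a degenerate sample (zero
  # spread) hits the bandwidth floor instead of bw.nrd0's fallbacks
  spread <- min(stats::sd(values), stats::IQR(values) / 1.34)
  bw <- max(0.9 * spread * length(values)^(-1 / 5), bw_floor)
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      from = 0, to = 1, n = n_grid)
  i <- which.max(d$y)  # first index: ties resolve to the smallest point
  # substantial local maxima (>= 5% of the global peak); tiny wiggles in
  # near-zero tails are not stability concerns
  dy <- diff(d$y)
  peak_idx <- which(diff(sign(dy)) < 0) + 1
  n_peaks <- sum(d$y[peak_idx] >= 0.05 * d$y[i])
  if (n_peaks > 1)
    message("density has ", n_peaks, " local maxima; the global mode ",
            "was taken - consider varying the number of iDMCs")
  list(mode = d$x[i], peak_height = d$y[i], bandwidth = bw)
}

#' Estimate tumor purity per sample
#'
#' For each tumor sample, iDMC beta values are direction-transformed with
#' [transform_idmc_betas()] and the purity estimate is the mode of their
#' Gaussian kernel density ([density_mode()]). Estimation is strictly
#' per-sample: a sample's estimate depends only on its own column and the
#' iDMC set. Samples that fail (e.g. too many missing iDMCs) are reported
#' with `NA` purity while the remaining samples are still estimated.
#'
#' @param beta A [beta_matrix()] containing the tumor samples.
#' @param groups A [sample_groups()]; only `tumor_ids` is used.
#' @param idmc An `idmc_set`.
#' @return A data frame of class `"purity_estimate"` with columns
#'   `sample_id`, `purity`, `n_idmc_used`, `peak_height`.
#' @export
estimate_purity <- function(beta, groups, idmc) {
  check_groups(beta, groups)
  stopifnot(inherits(idmc, "idmc_set"))
  if (!length(groups$tumor_ids)) stop("no tumor samples given")
  res <- lapply(groups$tumor_ids, function(s) {
    tryCatch({
      v <- transform_idmc_betas(beta[, s], idmc)
      dm <- density_mode(v)
      list(purity = min(max(dm$mode, 0), 1), n = length(v),
           h = dm$peak_height)
    }, error = function(e) {
      warning("purity estimation failed for sample '", s, "': ",
              conditionMessage(e), call. = FALSE)
      list(purity = NA_real_, n = 0L, h = NA_real_)
    })
  })
  out <- data.frame(
    sample_id = groups$tumor_ids,
    purity = vapply(res, `[[`, numeric(1), "purity"),
    n_idmc_used = vapply(res, function(r) as.integer(r$n), integer(1)),
    peak_height = vapply(res, `[[`, numeric(1), "h"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("purity_estimate", "data.frame")
  out
}

#' @export
print.purity_estimate <- function(x, ...) {
  ok <- !is.na(x$purity)
  cat("Tumor purity estimates for", nrow(x), "sample(s)",
      if (any(!ok)) paste0("(", sum(!ok), " failed)") else "", "\n")
  if (any(ok))
    cat("  purity: median ", format(stats::median(x$purity[ok]),
                                    digits = 3),
        ", range [", format(min(x$purity[ok]), digits = 3), ", ",
        format(max(x$purity[ok]), digits = 3), "]\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more row(s)\n")
  invisible(x)
}

# Named purity vector from a purity_estimate or a named vector.
as_purity_vector <- function(purity) {
  if (inherits(purity, "purity_estimate")) {
    lam <- purity$purity
    names(lam) <- purity$sample_id
    lam <- lam[!is.na(lam)]
  } else {
    lam <- purity
  }
  validate_purity(lam)
}
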