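#' Configuration for the synthetic methylation generator
#'
#' Defaults describe a mid-sized cancer methylation cohort: 2000 CpG
#' sites with a bimodal baseline methylome (modes near beta 0.1 and 0.9),
#' 50 tumor and 20 normal samples, purities uniform on (0.3, 0.9), 10%
#' true DMCs whose effects are large enough to serve as purity markers
#' (|delta| ~ N(2, 0.2^2) on the arcsine scale, i.e. roughly a 0.1 to
#' 0.9 swing on the beta scale), technical noise sd 0.05 on the arcsine
#' scale, and a moderate negative association between baseline
#' methylation and effect direction (unmethylated sites tend to gain,
#' methylated sites tend to lose methylation).
#'
#' @param n_sites Number of CpG sites.
#' @param n_tumor,n_normal Sample counts.
#' @param frac_dmc Fraction of sites that are true DMCs.
#' @param effect_mean,effect_sd Mean and sd of the effect magnitude
#'   |delta| on the arcsine scale (draws truncated at 0).
#' @param purity_range Range of the uniform purity distribution.
#' @param noise_sd Technical noise sd on the arcsine scale (> 0).
#' @param x_delta_corr Baseline-effect association in \[-1, 1\]; the
#'   probability that a DMC's effect opposes its baseline methylation
#'   state is (1 - x_delta_corr) / 2, so -1 means "always opposing"
#'   (hypermethylation of unmethylated sites and vice versa) and 0 means
#'   random signs.
#' @param baseline_modes Beta-scale locations of the two baseline modes.
#' @param baseline_sd Spread of baselines around each mode, arcsine
#'   scale.
#' @param scale `"beta"` (default): mixing of the normal and pure-cancer
#'   methylomes is a weighted average on the beta scale, the physically
#'   literal reading; `"arcsine"`: mixing on the transformed scale, where
#'   the linear model is exact.
#' @param seed Integer seed for reproducibility.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_sites = 2000, n_tumor = 50, n_normal = 20,
                         frac_dmc = 0.1, effect_mean = 2.0,
                         effect_sd = 0.2, purity_range = c(0.3, 0.9),
                         noise_sd = 0.05, x_delta_corr = -0.3,
                         baseline_modes = c(0.1, 0.9),
                         baseline_sd = 0.15,
                         scale = c("beta", "arcsine"), seed = 1L) {
  scale <- match.arg(scale)
  cfg <- list(n_sites = as.integer(n_sites),
              n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal),
              frac_dmc = frac_dmc, effect_mean = effect_mean,
              effect_sd = effect_sd, purity_range = purity_range,
              noise_sd = noise_sd, x_delta_corr = x_delta_corr,
              baseline_modes = baseline_modes,
              baseline_sd = baseline_sd, scale = scale,
              seed = as.integer(seed))
  if (cfg$n_sites < 1 || cfg$n_tumor < 1 || cfg$n_normal < 0)
    stop("invalid dimensions in synth_config")
  if (cfg$frac_dmc < 0 || cfg$frac_dmc > 1)
    stop("'frac_dmc' must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (cfg$x_delta_corr < -1 || cfg$x_delta_corr > 1)
    stop("'x_delta_corr' must lie in [-1, 1]")
  if (length(cfg$purity_range) != 2 || cfg$purity_range[1] <= 0 ||
      cfg$purity_range[2] > 1 ||
      cfg$purity_range[1] > cfg$purity_range[2])
    stop("'purity_range' must be an increasing pair within (0, 1]")
  if (any(cfg$baseline_modes <= 0 | cfg$baseline_modes >= 1))
    stop("'baseline_modes' must lie strictly inside (0, 1)")
  class(cfg) <- "synth_config"
  cfg
}

# clamp transformed values into the arcsine range, counting clamps
clamp_arcsine <- function(t) pmin(pmax(t, -pi / 2), pi / 2)

#' Generate a synthetic beta matrix with known truth
#'
#' Simulates the two-compartment mixture that purity-aware methylation
#' analysis assumes. Per site a baseline transformed mean m is drawn from
#' a two-component (bimodal) distribution; true DMC sites get an effect
#' delta whose sign follows the configured baseline-effect association.
#' Each tumor sample has purity lambda, and its noiseless signal is the
#' lambda-weighted average of the normal and pure-cancer methylomes
#' (on the beta or arcsine scale per `config$scale`). Technical noise is
#' added on the arcsine scale, values are clamped to the valid range,
#' and mapped back to beta values. Normal samples are baseline plus
#' noise. Effects emitted in the truth table are the *realized* ones
#' after boundary clamping of the pure-cancer methylome.
#'
#' @param config A [synth_config()].
#' @return A list of class `"meth_sim"` with elements `beta`
#'   (a [beta_matrix()], tumors then normals), `groups`
#'   (a [sample_groups()]), `truth` (list: `purity` named vector,
#'   `sites` data frame with `site_id`, `is_dmc`, `true_mu`,
#'   `direction`), and `config`.
#' @export
simulate_methylation <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  M <- config$n_sites; n1 <- config$n_tumor; n0 <- config$n_normal

  site_ids <- sprintf("cg%06d", seq_len(M))
  tumor_ids <- sprintf("T%03d", seq_len(n1))
  normal_ids <- if (n0 > 0) sprintf("N%03d", seq_len(n0)) else character()

  mode_t <- arcsine_transform(config$baseline_modes)
  comp <- sample.int(2, M, replace = TRUE)
  m <- stats::rnorm(M, mean = mode_t[comp], sd = config$baseline_sd)
  m <- clamp_arcsine(m)

  is_dmc <- rep(FALSE, M)
  n_dmc <- round(config$frac_dmc * M)
  if (n_dmc > 0) is_dmc[sample.int(M, n_dmc)] <- TRUE
  mag <- pmax(stats::rnorm(M, config$effect_mean, config$effect_sd), 0)
  p_oppose <- (1 - config$x_delta_corr) / 2
  oppose <- stats::runif(M) < p_oppose
  sgn <- ifelse(oppose, -sign(m), sign(m))
  sgn[sgn == 0] <- 1
  delta <- ifelse(is_dmc, sgn * mag, 0)

  # realized pure-cancer mean after clamping to the valid range
  t_pure <- clamp_arcsine(m + delta)
  delta_real <- t_pure - m

  lambda <- stats::runif(n1, config$purity_range[1],
                         config$purity_range[2])
  names(lambda) <- tumor_ids

  noise <- function(n) stats::rnorm(n, 0, config$noise_sd)
  if (config$scale == "beta") {
    x_beta <- inverse_arcsine(m)
    y_beta <- inverse_arcsine(t_pure)
    mix_beta <- outer(1 - lambda, x_beta) + outer(lambda, y_beta)
    tum_t <- arcsine_transform(mix_beta)        # samples x sites
  } else {
    tum_t <- outer(lambda, delta_real) +
      matrix(m, nrow = n1, ncol = M, byrow = TRUE)
  }
  tum_t <- tum_t + matrix(noise(n1 * M), nrow = n1)
  tum_beta <- inverse_arcsine(tum_t)

  if (n0 > 0) {
    norm_t <- matrix(m, nrow = n0, ncol = M, byrow = TRUE) +
      matrix(noise(n0 * M), nrow = n0)
    norm_beta <- inverse_arcsine(norm_t)
    values <- cbind(t(tum_beta), t(norm_beta))
  } else {
    values <- t(tum_beta)
  }

  beta <- beta_matrix(values, site_ids = site_ids,
                      sample_ids = c(tumor_ids, normal_ids))
  groups <- sample_groups(tumor_ids, normal_ids)
  sites <- data.frame(site_id = site_ids, is_dmc = is_dmc,
                      true_mu = delta_real,
                      direction = ifelse(!is_dmc, "none",
                                         ifelse(delta_real >= 0,
                                                "hyper", "hypo")),
                      stringsAsFactors = FALSE)
  structure(list(beta = beta, groups = groups,
                 truth = list(purity = lambda, sites = sites),
                 config = config),
            class = "meth_sim")
}

#' @export
print.meth_sim <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic methylation data:", cfg$n_sites, "sites,",
      cfg$n_tumor, "tumor +", cfg$n_normal, "normal samples\n")
  cat("  true DMCs:", sum(x$truth$sites$is_dmc),
      "; purity range [", format(min(x$truth$purity), digits = 3), ", ",
      format(max(x$truth$purity), digits = 3), "]; mixing on the ",
      cfg$scale, " scale; seed ", cfg$seed, "\n", sep = "")
  invisible(x)
}
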