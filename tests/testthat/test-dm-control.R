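test_that("arcsine transform hits its closed-form anchors", {
  expect_equal(arcsine_transform(0.5), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0), -pi / 2)
  expect_equal(arcsine_transform(0.75), pi / 6)
  v <- runif(50)
  expect_equal(MethylPurity:::inverse_arcsine(arcsine_transform(v)), v)
  expect_error(arcsine_transform(1.01), "\\[0, 1\\]")
})

test_that("the purity design stacks normals first with purity column", {
  g <- sample_groups(c("T1", "T2"), c("N1", "N2"))
  d <- build_design(g, c(T1 = 0.5, T2 = 0.8))
  expect_equal(unname(d$W),
               cbind(c(1, 1, 1, 1), c(0, 0, 0.5, 0.8)))
  expect_equal(d$sample_order, c("N1", "N2", "T1", "T2"))

  # all purities 1: the design collapses to the two-group indicator
  d1 <- build_design(g, c(T1 = 1, T2 = 1))
  expect_equal(unname(d1$W[, 2]), c(0, 0, 1, 1))

  # constant purity is estimable as long as normals anchor the baseline
  d2 <- build_design(g, c(T1 = 0.6, T2 = 0.6))
  expect_equal(qr(d2$W)$rank, 2)

  expect_error(build_design(g, c(T1 = 0.5)), "T2")
  expect_error(build_design(sample_groups(c("T1", "T2")),
                            c(T1 = 0.6, T2 = 0.6)), "rank deficient")
})

test_that("fit_site solves the normal equation exactly on noiseless data", {
  g <- sample_groups(paste0("T", 1:4), paste0("N", 1:4))
  d <- build_design(g, setNames(rep(1, 4), paste0("T", 1:4)))
  z <- c(rep(0, 4), rep(0.4, 4))
  fit <- fit_site(z, d)
  expect_equal(fit$mu_hat, 0.4)
  expect_equal(fit$m_hat, 0)

  # constant purity, noiseless difference d on the pure scale
  lam0 <- 0.6
  dd <- build_design(g, setNames(rep(lam0, 4), paste0("T", 1:4)))
  true_d <- 0.5
  z2 <- c(rep(0.2, 4), rep(0.2 + lam0 * true_d, 4))
  fit2 <- fit_site(z2, dd)
  expect_equal(fit2$mu_hat, true_d)
  expect_equal(fit2$m_hat + lam0 * fit2$mu_hat, 0.2 + lam0 * true_d)
})

test_that("fit_site matches the explicit 2x2-inverse oracle", {
  set.seed(51)
  for (i in 1:200) {
    n0 <- sample(3:8, 1); n1 <- sample(3:10, 1)
    g <- sample_groups(paste0("T", seq_len(n1)),
                       paste0("N", seq_len(n0)))
    lam <- setNames(runif(n1, 0.2, 1), paste0("T", seq_len(n1)))
    d <- build_design(g, lam)
    z <- rnorm(n0 + n1)
    fit <- fit_site(z, d)
    orc <- oracle_fit(z, d$W, n0, n1)
    expect_equal(fit$mu_hat, orc$beta[2], tolerance = 1e-10)
    expect_equal(fit$m_hat, orc$beta[1], tolerance = 1e-10)
    expect_equal(fit$var_beta, orc$var_beta, tolerance = 1e-10)
    expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-10)
    expect_equal(fit$sigma2_prime, orc$sigma2_prime, tolerance = 1e-10)
  }
})

test_that("variance shrinkage has its closed-form limits", {
  v <- c(0.5, 2, 8)
  expect_equal(shrink_variances(v, weight = 0), v)
  expect_equal(shrink_variances(v, weight = 1),
               rep(exp(mean(log(v))), 3))
  expect_equal(shrink_variances(c(1, 4), weight = 0.5),
               c(sqrt(2), 2 * sqrt(2)))
  expect_error(shrink_variances(v, weight = 1.2), "\\[0, 1\\]")

  # the geometric mean is invariant for every weight
  set.seed(52)
  x <- rexp(40)
  for (w in c(0.1, 0.37, 0.8))
    expect_equal(exp(mean(log(shrink_variances(x, w)))),
                 exp(mean(log(x))))
  expect_message(shrink_variances(c(1, 0, 4), 0.2), "floored")
})

test_that("the Wald test follows t with n0 + n1 - 2 df", {
  expect_equal(wald_test(0, 1, 5, 5)$p_value, 1)
  wt <- wald_test(2, 1, 6, 6)  # t = 2, df = 10
  expect_equal(wt$p_value, 0.07338803, tolerance = 1e-6)
  expect_warning(wt0 <- wald_test(c(0, 0.3), c(0, 0), 5, 5),
                 "zero standard error")
  expect_equal(wt0$p_value, c(1, 0))
})

test_that("with purity 1 the model reduces to the two-group statistic", {
  set.seed(53)
  n0 <- 8; n1 <- 9
  g <- sample_groups(paste0("T", seq_len(n1)), paste0("N", seq_len(n0)))
  vals <- matrix(runif(60 * (n0 + n1), 0.2, 0.8), 60,
                 dimnames = list(paste0("cg", 1:60),
                                 c(paste0("T", seq_len(n1)),
                                   paste0("N", seq_len(n0)))))
  b <- beta_matrix(vals)
  res <- call_dm(b, g, setNames(rep(1, n1), paste0("T", seq_len(n1))),
                 shrink_weight = 0)
  Z <- arcsine_transform(vals)
  tum <- Z[res$site_id, paste0("T", seq_len(n1))]
  ctl <- Z[res$site_id, paste0("N", seq_len(n0))]
  mu <- rowMeans(tum) - rowMeans(ctl)
  s2 <- (n0 - 1) * apply(ctl, 1, var) / (n0 - 2)
  s2p <- (n1 - 1) * apply(tum, 1, var) / (n1 - 2)
  t_ref <- mu / sqrt(s2 / n0 + s2p / n1)
  expect_equal(res$t, unname(t_ref), tolerance = 1e-10)
  expect_equal(res$mu_hat, unname(mu), tolerance = 1e-10)
})

test_that("purity acts multiplicatively: rescaling lambda rescales mu", {
  set.seed(54)
  n0 <- 6; n1 <- 10
  g <- sample_groups(paste0("T", seq_len(n1)), paste0("N", seq_len(n0)))
  lam <- setNames(runif(n1, 0.5, 1), paste0("T", seq_len(n1)))
  m <- 0.1; mu <- 0.45
  z <- c(rep(m, n0), m + lam * mu)  # noiseless mixture responses
  for (k in c(0.5, 0.25)) {
    fit_full <- fit_site(z, build_design(g, lam))
    fit_scaled <- fit_site(z, build_design(g, k * lam))
    expect_equal(fit_scaled$mu_hat, fit_full$mu_hat / k,
                 tolerance = 1e-10)
  }
})

test_that("calling is invariant to site order and BH is monotone", {
  sim <- simulate_methylation(
    synth_config(n_sites = 300, n_tumor = 10, n_normal = 8,
                 frac_dmc = 0.2, effect_mean = 0.5, effect_sd = 0,
                 noise_sd = 0.2, seed = 55))
  res <- call_dm(sim$beta, sim$groups, sim$truth$purity)
  perm <- sample(nrow(sim$beta))
  b2 <- beta_matrix(unclass(sim$beta)[perm, ],
                    site_ids = rownames(sim$beta)[perm],
                    sample_ids = colnames(sim$beta))
  res2 <- call_dm(b2, sim$groups, sim$truth$purity)
  res2 <- res2[match(res$site_id, res2$site_id), ]
  expect_equal(res$p, res2$p)
  expect_equal(res$fdr, res2$fdr)
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  expect_true(all(res$fdr >= res$p - 1e-12))
})

test_that("degenerate zero-variance sites are flagged, not NaN", {
  n0 <- 4; n1 <- 4
  g <- sample_groups(paste0("T", 1:n1), paste0("N", 1:n0))
  vals <- rbind(c(rep(0.2, n1), rep(0.2, n0)),   # mu = 0, no noise
                c(rep(0.9, n1), rep(0.1, n0)),   # mu != 0, no noise
                runif(n0 + n1, 0.3, 0.7))
  b <- beta_matrix(vals, site_ids = c("null0", "det1", "noisy"),
                   sample_ids = c(paste0("T", 1:n1), paste0("N", 1:n0)))
  expect_warning(
    res <- call_dm(b, g, setNames(rep(1, n1), paste0("T", 1:n1))),
    "degenerate")
  expect_equal(res$flag[res$site_id == "null0"], "degenerate")
  expect_equal(res$p[res$site_id == "null0"], 1)
  expect_equal(res$p[res$site_id == "det1"], 0)
  expect_false(anyNA(res$p))
})

test_that("sites with missing values are dropped from DM calling", {
  set.seed(56)
  n0 <- 4; n1 <- 5
  vals <- matrix(runif(20 * (n0 + n1), 0.2, 0.8), 20,
                 dimnames = list(paste0("cg", 1:20),
                                 c(paste0("T", 1:n1), paste0("N", 1:n0))))
  vals[3, 2] <- NA
  b <- beta_matrix(vals)
  g <- sample_groups(paste0("T", 1:n1), paste0("N", 1:n0))
  expect_message(
    res <- call_dm(b, g, setNames(runif(n1, 0.4, 0.9),
                                  paste0("T", 1:n1))),
    "1 site")
  expect_equal(nrow(res), 19)
  expect_false("cg3" %in% res$site_id)
})
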