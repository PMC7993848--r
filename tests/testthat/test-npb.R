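# The enumeration oracle (helper-fixtures.R) fixes all hyperparameters and
# compares the sampler's posterior mass on each zero/cluster configuration
# of a two-coefficient problem with exact brute-force integration.

test_that("two-coefficient configuration posterior matches brute-force enumeration", {
  skip_if_not_installed("mvtnorm")
  set.seed(42)
  n <- 6
  x1 <- rnorm(n); x2 <- 0.6 * x1 + 0.8 * rnorm(n)
  y <- 0.8 * x1 + rnorm(n)
  X <- mixbench:::new_exposure_table(cbind(x1 = x1, x2 = x2))
  W <- mixbench:::new_covariate_table(matrix(0, n, 0), character(0))
  ds <- manual_ds(y, X, W)
  alpha <- 1; pi0 <- 0.4; mu <- 0.3; phi2 <- 1; sigma2 <- 1; gvar <- 4

  exact <- enumerate_npb_configs(y, x1, x2, alpha, pi0, mu, phi2, sigma2, gvar)
  fit <- fit_npbr(ds, npb_priors(gamma_var = gvar),
                  n_burn = 2000, n_keep = 40000, seed = 303,
                  fix = list(alpha = alpha, pi0 = pi0, mu = mu,
                             phi2 = phi2, sigma2 = sigma2))
  cls <- classify_draws(fit)
  nb <- 100
  batches <- split(cls, rep(seq_len(nb), each = length(cls) / nb))
  for (cfg in names(exact)) {
    freq <- vapply(batches, function(b) mean(b == cfg), 0)
    se <- sd(freq) / sqrt(nb)
    expect_lt(abs(mean(freq) - exact[[cfg]]), 3 * se + 0.004,
              label = sprintf("config %s: sampler %.4f vs exact %.4f (se %.4f)",
                              cfg, mean(freq), exact[[cfg]], se))
  }
})

test_that("PIPs are the fraction of nonzero retained draws", {
  fake <- structure(
    list(beta = cbind(a = c(0, 0, 1.2, 0, 0.8), b = rep(0, 5), c = rep(2, 5)),
         block = c(1L, 1L, 1L), exposure_names = c("a", "b", "c"),
         pairs = matrix(integer(0), 0, 2)),
    class = "npb_fit")
  pp <- pips(fake)
  expect_equal(unname(pp$main), c(0.4, 0, 1))
})

test_that("forcing the point mass gives an all-zero posterior", {
  X <- toy_exposures(60, p = 3, seed = 3)
  W <- toy_covariates(60)
  ds <- simulate_dataset(X, W, scenario_config("null", seed = 4))
  fit <- fit_npbr(ds, n_burn = 100, n_keep = 300, seed = 5,
                  fix = list(pi0 = 1))
  expect_true(all(fit$beta == 0))
  expect_true(all(pips(fit)$main == 0))
})

test_that("zeros are exact and cluster members share bit-identical values", {
  X <- toy_exposures(100, p = 5, seed = 6)
  W <- toy_covariates(100)
  set.seed(7)
  y <- 2 * X$values[, 1] + 2 * X$values[, 2] + rnorm(100)
  ds <- manual_ds(y, X, W, active = 1:2, h_true = 2 * rowSums(X$values[, 1:2]))
  fit <- fit_npbr(ds, n_burn = 300, n_keep = 500, seed = 8)
  nz <- fit$beta[fit$beta != 0]
  expect_true(all(abs(nz) > 1e-300))
  for (t in c(1, 250, 500)) {
    lab <- fit$labels[t, ]
    for (k in unique(lab[lab >= 0])) {
      vals <- fit$beta[t, lab == k]
      expect_true(all(vals == vals[1]))
    }
  }
})

test_that("a single strong effect is detected with clean PIP separation", {
  X <- gen_exposures(153, cached_spec(), seed = 31)
  W <- gen_covariates(153, seed = 32)
  set.seed(33)
  gam <- rnorm(W$q)
  y <- 3 * X$values[, 1] + drop(W$values %*% gam) + rnorm(153)
  ds <- manual_ds(y, X, W, active = 1L, h_true = 3 * X$values[, 1], gamma = gam)
  fit <- fit_npbr(ds, n_burn = 500, n_keep = 500, seed = 34)
  pp <- pips(fit)$main
  expect_gt(pp[1], 0.9)
  expect_lt(median(pp[-1]), 0.5)
})

test_that("h reconstruction reduces to the linear predictor draw-wise", {
  X <- toy_exposures(30, p = 3, seed = 9)
  W <- toy_covariates(30)
  ds <- simulate_dataset(X, W, scenario_config("null", seed = 10))
  fit <- fit_npbr(ds, n_burn = 50, n_keep = 100, seed = 11)

  # all-zero draws: degenerate zero surface
  fake <- fit
  fake$beta <- matrix(0, 100, 3)
  est0 <- estimate_h(fake, center = FALSE)
  expect_equal(est0$mean, rep(0, 30))
  expect_equal(est0$lo, rep(0, 30)); expect_equal(est0$hi, rep(0, 30))

  # single draw beta = (1, 0, 0): h is exactly the first exposure
  fake$beta <- matrix(c(1, 0, 0), 1, 3)
  est1 <- estimate_h(fake, center = FALSE)
  expect_equal(est1$mean, unname(X$values[, 1]))

  est <- estimate_h(fit)
  expect_true(all(est$lo <= est$mean + 1e-12 & est$mean <= est$hi + 1e-12))
  expect_equal(mean(est$mean), 0, tolerance = 1e-12) # centering convention
})

test_that("interaction block is present only in the interaction variant", {
  X <- toy_exposures(80, p = 4, seed = 12)
  W <- toy_covariates(80)
  ds <- simulate_dataset(X, W, scenario_config("null", seed = 13))
  fit <- fit_npb(ds, n_burn = 100, n_keep = 100, seed = 14)
  expect_equal(ncol(fit$beta), 4 + 6)
  expect_equal(nrow(fit$pairs), 6)
  fitr <- fit_npbr(ds, n_burn = 100, n_keep = 100, seed = 14)
  expect_equal(ncol(fitr$beta), 4)
  expect_error(fit_npb(ds, n_keep = 0, seed = 1), "n_keep")
})
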