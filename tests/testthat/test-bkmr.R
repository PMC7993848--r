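test_that("the Gaussian kernel has exact closed-form entries", {
  X <- rbind(c(1, 2), c(1, 2), c(0, 0))
  K <- gaussian_kernel(X, c(1, 1))
  expect_equal(K[1, 2], 1)            # identical rows
  expect_equal(diag(K), rep(1, 3))
  expect_equal(gaussian_kernel(X, c(0, 0)), matrix(1, 3, 3))
  expect_equal(gaussian_kernel(matrix(c(0, 0.5), 2, 1), 2)[1, 2], exp(-0.5))
  expect_error(gaussian_kernel(X, c(-1, 1)), "nonnegative")
})

test_that("sampled kernels are PSD with unit diagonal", {
  set.seed(1)
  X <- matrix(rnorm(30 * 4), 30, 4)
  for (i in 1:10) {
    r <- rexp(4) * rbinom(4, 1, 0.6)
    K <- gaussian_kernel(X, r)
    expect_equal(diag(K), rep(1, 30))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("the marginal likelihood matches a naive dense computation", {
  set.seed(2)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  e <- rnorm(n)
  for (i in 1:5) {
    r <- rexp(3); lambda <- rexp(1, 0.2); sigma2 <- runif(1, 0.3, 2)
    K <- gaussian_kernel(X, r)
    got <- mixbench:::bkmr_loglik(e, K, lambda, sigma2)$ll
    A <- sigma2 * (diag(n) + lambda * K)
    naive <- -0.5 * determinant(A)$modulus[1] - 0.5 * drop(e %*% solve(A, e))
    expect_equal(got, naive, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("conditional h mean equals the direct Gaussian-process formula", {
  set.seed(3)
  X <- matrix(rnorm(5 * 2), 5, 2)
  e <- rnorm(5)
  r <- c(0.5, 1.2); lambda <- 3; sigma2 <- 0.7
  K <- gaussian_kernel(X, r)
  eig <- eigen(K, symmetric = TRUE)
  got <- mixbench:::h_draw_spectral(eig, lambda, sigma2, e, rep(0, 5))
  direct <- lambda * K %*% solve(diag(5) + lambda * K, e)
  expect_equal(got, drop(direct), tolerance = 1e-10)
})

test_that("a vanishing signal-to-noise ratio flattens the surface", {
  set.seed(4)
  n <- 30
  X <- toy_exposures(n, p = 3, seed = 5)
  W <- toy_covariates(n, seed = 6)
  ds <- simulate_dataset(X, W, scenario_config("null", seed = 7))
  fit <- fit_bkmr(ds, n_burn = 100, n_keep = 100, seed = 8)
  fake <- fit
  fake$lambda <- rep(1e-12, fit$n_keep)
  est <- posterior_h(fake, center = FALSE, seed = 9)
  expect_lt(max(abs(est$mean)), 1e-4)
  expect_lt(max(est$hi - est$lo), 1e-4)
})

test_that("PIPs count positive kernel weights; inactive profiles are flat", {
  fake <- structure(
    list(r = cbind(a = c(0.2, 0.4, 0.1), b = rep(0, 3)),
         n_keep = 3, exposure_names = c("a", "b")),
    class = "bkmr_fit")
  expect_equal(pips(fake), c(a = 1, b = 0))
  expect_equal(selected_terms(fake)$main, 1L)

  set.seed(10)
  n <- 30
  X <- toy_exposures(n, p = 2, seed = 11)
  W <- toy_covariates(n, seed = 12)
  ds <- simulate_dataset(X, W, scenario_config("null", seed = 13))
  fit <- fit_bkmr(ds, n_burn = 50, n_keep = 50, seed = 14)
  fit$r[, 2] <- 0 # force exposure 2 out of every draw
  prof <- univariate_profile(fit, 2, grid = seq(-1, 1, length.out = 5),
                             seed = 15)
  expect_lt(diff(range(prof$mean)), 1e-8)
  expect_false(any(prof$extrapolated[2:4]))
})

test_that("active components of a linear mixture are selected and covered", {
  X <- gen_exposures(80, cached_spec(), seed = 21)
  W <- gen_covariates(80, seed = 22)
  ds <- simulate_dataset(X, W, scenario_config("linear", seed = 23))
  fit <- fit_bkmr(ds, n_burn = 500, n_keep = 500, seed = 24)
  sr <- selection_rates(selected_terms(fit)$main, ds$active, 7)
  expect_gte(sr["tsr"], 0.75)
  est <- posterior_h(fit, seed = 25)
  expect_gt(coverage_h(ds$h_true, est), 0.85)
  expect_lt(rmse_h(ds$h_true, est), 1)
})

test_that("null data keep the mean PIP near the prior inclusion probability", {
  # per-dataset PIPs under a null likelihood are noise-driven, so the
  # calibration statement is about the average across null datasets;
  # pi ~ Beta(1, 1) makes the prior inclusion probability 0.5
  pip_means <- vapply(1:5, function(k) {
    X <- toy_exposures(60, p = 7, seed = 30 + k)
    W <- toy_covariates(60, seed = 40 + k)
    ds <- simulate_dataset(X, W, scenario_config("null", seed = 50 + k))
    fit <- fit_bkmr(ds, n_burn = 800, n_keep = 800, seed = 60 + k)
    mean(pips(fit))
  }, 0)
  expect_gt(mean(pip_means), 0.3)
  expect_lt(mean(pip_means), 0.7)
})
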