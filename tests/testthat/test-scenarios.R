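test_that("the linear exposure-response form evaluates exactly", {
  expect_equal(h_linear(0, 0, 0, 0), 0)
  expect_equal(h_linear(1, 1, 1, 1), 0.2)
  expect_equal(h_linear(1, 0, 0, 0), 1)
})

test_that("the sigmoidal form has the right center and saturation limits", {
  expect_equal(h_nonlinear(0, 0, 0), 1)
  expect_equal(h_nonlinear(50, 0, 0), 2, tolerance = 1e-12)
  expect_equal(h_nonlinear(-50, 0, 0), 0, tolerance = 1e-12)
})

test_that("fixed profiles assign the four constants with ties going low", {
  expect_equal(h_profiles(-1, -1, 0, 0), -2)
  expect_equal(h_profiles(-1, 1, 0, 0), -1)
  expect_equal(h_profiles(1, -1, 0, 0), 0)
  expect_equal(h_profiles(1, 1, 0, 0), 2)
  expect_equal(h_profiles(0, 1, 0, 0), -1)  # x1 exactly at the median
})

test_that("fixed profiles split continuous data at the medians", {
  x <- toy_exposures(101, p = 2, seed = 8)
  h <- h_profiles(x$values[, 1], x$values[, 2],
                  median(x$values[, 1]), median(x$values[, 2]))
  expect_true(all(h %in% c(-2, -1, 0, 2)))
  lo1 <- sum(x$values[, 1] <= median(x$values[, 1]))
  expect_equal(lo1, 51)  # ceiling(n/2) on the "<=" side at odd n
})

test_that("simulation honors scenario structure, noise and determinism", {
  X <- toy_exposures(120, p = 5, seed = 1)
  W <- toy_covariates(120)

  d0 <- simulate_dataset(X, W, scenario_config("null", seed = 4))
  expect_equal(d0$h_true, rep(0, 120))
  expect_length(d0$active, 0)

  dn <- simulate_dataset(X, W, scenario_config("linear", noise_sd = 1e-9, seed = 4))
  expect_equal(dn$y - drop(W$values %*% dn$gamma), dn$h_true, tolerance = 1e-6)

  a <- simulate_dataset(X, W, scenario_config("linear", seed = 11))
  b <- simulate_dataset(X, W, scenario_config("linear", seed = 11))
  expect_identical(a$y, b$y); expect_identical(a$active, b$active)
  actives <- vapply(1:20, function(s) {
    paste(simulate_dataset(X, W, scenario_config("linear", seed = s))$active,
          collapse = ",")
  }, "")
  expect_gt(length(unique(actives)), 1)
  expect_false(anyDuplicated(a$active) > 0)

  # residual noise variance consistent with noise_sd = 1
  d <- simulate_dataset(X, W, scenario_config("linear", seed = 21))
  resid <- d$y - d$h_true - drop(W$values %*% d$gamma)
  expect_gt(var(resid) * 119, qchisq(1e-6, 119))
  expect_lt(var(resid) * 119, qchisq(1 - 1e-6, 119))

  X3 <- toy_exposures(50, p = 3, seed = 2)
  W3 <- toy_covariates(50)
  expect_error(simulate_dataset(X3, W3, scenario_config("linear", seed = 1)),
               "active")
})

test_that("active interaction pairs follow the scenario definitions", {
  X <- toy_exposures(60, p = 5, seed = 1)
  W <- toy_covariates(60)
  dl <- simulate_dataset(X, W, scenario_config("linear", seed = 2))
  pl <- active_interactions(dl)
  expect_equal(nrow(pl), 2)
  expect_equal(sort(pl[1, ]), sort(dl$active[1:2]))
  dnl <- simulate_dataset(X, W, scenario_config("nonlinear", seed = 2))
  expect_equal(nrow(active_interactions(dnl)), 1)
  expect_equal(nrow(active_interactions(
    simulate_dataset(X, W, scenario_config("null", seed = 2)))), 0)
})

test_that("datasets serialize to CSV + JSON and reload exactly", {
  X <- toy_exposures(25, p = 3, seed = 5)
  W <- toy_covariates(25)
  ds <- simulate_dataset(X, W, scenario_config("nonlinear", seed = 6))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$y, ds$y, tolerance = 1e-12)
  expect_equal(back$X$values, ds$X$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$active, ds$active)
  expect_equal(back$scenario_id, ds$scenario_id)
  expect_equal(back$h_true, ds$h_true, tolerance = 1e-12)
})

test_that("the complex scenario runs on the doubled 14-exposure mixture", {
  spec14 <- complex_spec(cached_spec())
  X <- gen_exposures(80, spec14, seed = 3)
  W <- toy_covariates(80)
  ds <- simulate_dataset(X, W, scenario_config("complex", seed = 5))
  expect_equal(ds$X$p, 14)
  expect_length(ds$active, 4)
  xa <- X$values[, ds$active]
  expect_equal(ds$h_true, h_linear(xa[, 1], xa[, 2], xa[, 3], xa[, 4]))
})
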