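test_that("standardization square-roots then z-scores, with exact hand case", {
  raw <- cbind(a = c(0, 1, 4), b = c(1, 4, 9))
  tab <- standardize_exposures(raw)
  # sqrt of column a is (0, 1, 2); z-scoring gives (-1, 0, 1)
  expect_equal(unname(tab$values[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(tab$values), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(tab$values, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
})

test_that("standardization rejects negative entries and constant columns", {
  expect_error(standardize_exposures(cbind(x = c(-1, 2, 3))), "nonnegative")
  expect_error(standardize_exposures(cbind(ok = c(1, 2, 3), flat = c(2, 2, 2))),
               "flat")
})

test_that("generated exposure columns meet the mean-0/SD-1 contract", {
  x <- gen_exposures(400, cached_spec(), seed = 5)
  expect_true(all(abs(colMeans(x$values)) < 1e-8))
  expect_true(all(abs(apply(x$values, 2, sd) - 1) < 1e-8))
  expect_false(anyNA(x$values))
})

test_that("same seed gives bit-identical exposures, different seeds differ", {
  a <- gen_exposures(60, cached_spec(), seed = 9)
  b <- gen_exposures(60, cached_spec(), seed = 9)
  c <- gen_exposures(60, cached_spec(), seed = 10)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_error(gen_exposures(1, cached_spec(), seed = 1), "at least 2")
})

test_that("an identity target yields near-zero sample rank correlations", {
  marg <- replicate(4, list(mean = 1, sd = 0.5, zero_mass = 0), simplify = FALSE)
  spec <- correlation_spec(paste0("x", 1:4), diag(4), marg)
  x <- gen_exposures(10000, spec, seed = 3)
  S <- cor(x$values, method = "spearman")
  expect_lt(max(abs(S[upper.tri(S)])), 0.03)
})

test_that("copula calibration reproduces the printed correlations, ties included", {
  spec <- cached_spec()
  x <- gen_exposures(10000, spec, seed = 17)
  S <- cor(x$values, method = "spearman")
  err <- abs(S - spec$rho)
  expect_lt(max(err[upper.tri(err)]), 0.05)
  expect_equal(S["NO2", "PM25"], 0.88, tolerance = 0.03 / 0.88)
  # zero-inflated marginals keep their point masses after standardization
  frac_at_min <- colMeans(sweep(x$values, 2, apply(x$values, 2, min), "==")
                          [, c("C", "MeBr", "OP")])
  expect_equal(unname(frac_at_min), c(0.65, 0.80, 0.30), tolerance = 0.05)
})

test_that("an inconsistent target matrix triggers the PSD repair", {
  rho <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  marg <- replicate(3, list(mean = 1, sd = 0.5, zero_mass = 0), simplify = FALSE)
  spec <- correlation_spec(c("a", "b", "c"), rho, marg)
  expect_true(spec$repaired)
  expect_gte(min(eigen(spec$latent, symmetric = TRUE)$values), 0)
  expect_silent(gen_exposures(50, spec, seed = 1))
})

test_that("spec validation catches malformed inputs", {
  marg2 <- replicate(2, list(mean = 1, sd = 1, zero_mass = 0), simplify = FALSE)
  bad <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(correlation_spec(c("a", "b"), bad, marg2), "symmetric")
  expect_error(correlation_spec(c("a", "b"), matrix(c(2, 0, 0, 1), 2), marg2),
               "diagonal")
  # heavy one-sided ties make a strong Spearman correlation unattainable
  margz <- list(list(mean = 1, sd = 4, zero_mass = 0.9),
                list(mean = 1, sd = 1, zero_mass = 0))
  expect_error(
    correlation_spec(c("a", "b"), matrix(c(1, 0.9, 0.9, 1), 2), margz),
    "unattainable")
})

test_that("the doubled complex-mixture spec has 14 calibrated components", {
  spec <- complex_spec(cached_spec(), between = 0.2)
  expect_equal(spec$p, 14)
  expect_equal(spec$rho[1:7, 1:7], cached_spec()$rho, ignore_attr = TRUE)
  expect_true(all(spec$rho[1:7, 8:14][row(diag(7)) != col(diag(7))] == 0.2))
})

test_that("exposure CSV loading is strict and round-trips exactly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  x <- gen_exposures(20, cached_spec(), seed = 4)
  write.csv(as.data.frame(x$values), tmp, row.names = FALSE)
  back <- load_exposure_csv(tmp, standardize = FALSE)
  expect_equal(back$values, x$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$names, x$names)

  writeLines(c("a,b", "1,2", "3,NA"), tmp)
  expect_error(load_exposure_csv(tmp), "row 2")
  writeLines(c("a,b", "1,2,3"), tmp)
  expect_error(load_exposure_csv(tmp), "ragged")
  writeLines(c("a,a", "1,2"), tmp)
  expect_error(load_exposure_csv(tmp), "duplicate")
})
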