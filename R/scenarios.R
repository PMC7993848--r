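# Outcome scenarios: exposure-response functions h1-h3 (plus null and
# complex-mixture variants) under the shared model
#   y_i = h(x_i) + w_i' gamma + eps_i,  eps_i ~ N(0, noise_sd^2).

#' Linear exposure-response function with two multiplicative interactions
#'
#' `h(x) = x1 - x2 + x3 - x4 + 0.7 x1 x2 - 0.5 x3 x4`, defined on four
#' (standardized) active exposures. Vectorized over its arguments.
#'
#' @param x1,x2,x3,x4 active exposure values.
#' @return Numeric vector of exposure-response values.
#' @export
h_linear <- function(x1, x2, x3, x4) {
  x1 - x2 + x3 - x4 + 0.7 * x1 * x2 - 0.5 * x3 * x4
}

#' Nonlinear (sigmoidal) exposure-response function
#'
#' `h(x) = 2/(1+exp(-3 x1)) + 2/(1+exp(-5 x2)) - 2/(1+exp(-5 x3))
#'  - 0.4 x1 x2`, combining saturating effects of three exposures with one
#' pairwise interaction.
#'
#' @param x1,x2,x3 active exposure values.
#' @return Numeric vector.
#' @export
h_nonlinear <- function(x1, x2, x3) {
  2 / (1 + exp(-3 * x1)) + 2 / (1 + exp(-5 * x2)) -
    2 / (1 + exp(-5 * x3)) - 0.4 * x1 * x2
}

#' Fixed-profiles exposure-response function
#'
#' Assigns a constant health effect to the four groups defined by the sample
#' medians of two active exposures: -2 (both at or below their medians),
#' -1 (only x2 above), 0 (only x1 above), and +2 (both above). Ties go to
#' the "<=" branch.
#'
#' @param x1,x2 active exposure values.
#' @param med1,med2 the corresponding sample medians (computed from the same
#'   dataset's active columns).
#' @return Numeric vector with values in \{-2, -1, 0, 2\}.
#' @export
h_profiles <- function(x1, x2, med1, med2) {
  lo1 <- x1 <= med1
  lo2 <- x2 <= med2
  ifelse(lo1 & lo2, -2, ifelse(lo1 & !lo2, -1, ifelse(!lo1 & lo2, 0, 2)))
}

scenario_ids <- c("linear", "nonlinear", "profiles", "null", "complex")

#' Scenario configuration
#'
#' @param scenario one of "linear", "nonlinear", "profiles", "null",
#'   "complex". The complex scenario applies the linear form to 4 active
#'   components of a 14-exposure mixture.
#' @param noise_sd residual SD (default 1).
#' @param seed integer seed controlling active-set sampling, covariate
#'   coefficients and noise.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(scenario = c("linear", "nonlinear", "profiles",
                                         "null", "complex"),
                            noise_sd = 1, seed = NULL) {
  scenario <- match.arg(scenario)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  n_active <- switch(scenario, linear = 4, nonlinear = 3, profiles = 2,
                     null = 0, complex = 4)
  structure(list(scenario_id = scenario, n_active = n_active,
                 noise_sd = noise_sd, seed = seed),
            class = "scenario_config")
}

#' Simulate an outcome vector under an exposure-response scenario
#'
#' Samples the active exposure indices uniformly without replacement (so each
#' simulated dataset has a different correlation structure among its active
#' components), draws covariate coefficients gamma ~ N(0, 1) i.i.d., computes
#' the true exposure-response vector via the scenario's h function, and adds
#' independent Gaussian noise. All randomness derives from `cfg$seed`.
#'
#' @param X an `exposure_table` (held fixed across replicates of a study).
#' @param W a `covariate_table`, row-aligned with `X`.
#' @param cfg a [scenario_config()].
#' @return A `simulated_dataset`: list with `y`, `X`, `W`, `active` (ordered
#'   indices playing the roles x1..xm), `h_true`, `gamma`, `scenario_id`,
#'   `noise_sd`, `seed`.
#' @export
simulate_dataset <- function(X, W, cfg) {
  stopifnot(inherits(X, "exposure_table"), inherits(W, "covariate_table"),
            inherits(cfg, "scenario_config"))
  if (X$n != W$n) stop("X and W must be row-aligned")
  if (cfg$n_active > X$p) stop("scenario needs more active exposures than available")
  with_seed(cfg$seed, function() {
    active <- if (cfg$n_active > 0) sample.int(X$p, cfg$n_active) else integer(0)
    gamma <- stats::rnorm(W$q)
    xa <- X$values[, active, drop = FALSE]
    h_true <- switch(cfg$scenario_id,
      linear = ,
      complex = h_linear(xa[, 1], xa[, 2], xa[, 3], xa[, 4]),
      nonlinear = h_nonlinear(xa[, 1], xa[, 2], xa[, 3]),
      profiles = h_profiles(xa[, 1], xa[, 2],
                            stats::median(xa[, 1]), stats::median(xa[, 2])),
      null = rep(0, X$n)
    )
    eps <- stats::rnorm(X$n, 0, cfg$noise_sd)
    y <- h_true + drop(W$values %*% gamma) + eps
    structure(
      list(y = y, X = X, W = W, active = active, h_true = h_true,
           gamma = gamma, scenario_id = cfg$scenario_id,
           noise_sd = cfg$noise_sd, seed = cfg$seed),
      class = "simulated_dataset"
    )
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: scenario '%s', n = %d, p = %d, q = %d\n",
              x$scenario_id, length(x$y), x$X$p, x$W$q))
  if (length(x$active)) {
    cat("  active exposures (x1..):",
        paste(x$X$names[x$active], collapse = ", "), "\n")
  }
  invisible(x)
}

#' True active interaction pairs of a scenario
#'
#' Linear/complex: \{x1x2, x3x4\}; nonlinear and fixed profiles: \{x1x2\};
#' null: none. Returned as a 2-column matrix of exposure indices.
#'
#' @param ds a `simulated_dataset`.
#' @return Matrix with one row per active unordered pair.
#' @export
active_interactions <- function(ds) {
  a <- ds$active
  pairs <- switch(ds$scenario_id,
    linear = ,
    complex = rbind(a[1:2], a[3:4]),
    nonlinear = ,
    profiles = rbind(a[1:2]),
    null = matrix(integer(0), 0, 2)
  )
  if (nrow(pairs)) t(apply(pairs, 1, sort)) else pairs
}

#' Serialize a simulated dataset to a directory of CSVs plus a JSON sidecar
#'
#' Writes `y.csv`, `X.csv`, `W.csv` and `meta.json` (scenario id, active
#' indices, gamma, noise SD, seed) so a dataset can be refit by external
#' tools or reloaded exactly.
#'
#' @param ds a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(y = ds$y), file.path(dir, "y.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ds$X$values), file.path(dir, "X.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ds$W$values), file.path(dir, "W.csv"),
                   row.names = FALSE)
  meta <- list(scenario_id = ds$scenario_id, active = ds$active,
               gamma = ds$gamma, h_true = ds$h_true,
               noise_sd = ds$noise_sd, seed = ds$seed,
               covariate_kinds = ds$W$kinds)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reload a dataset written by [write_dataset()]
#'
#' @param dir directory produced by [write_dataset()].
#' @return A `simulated_dataset`.
#' @export
read_dataset <- function(dir) {
  y <- read_numeric_csv(file.path(dir, "y.csv"))[, 1]
  Xv <- read_numeric_csv(file.path(dir, "X.csv"))
  Wv <- read_numeric_csv(file.path(dir, "W.csv"))
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  structure(
    list(y = y, X = new_exposure_table(Xv, provenance = "loaded"),
         W = new_covariate_table(Wv, meta$covariate_kinds),
         active = as.integer(meta$active), h_true = meta$h_true,
         gamma = meta$gamma, scenario_id = meta$scenario_id,
         noise_sd = meta$noise_sd, seed = meta$seed),
    class = "simulated_dataset"
  )
}
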