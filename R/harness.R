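# Simulation harness: scenario x method x replicate grid with derived
# per-replicate RNG streams, incremental (resumable) record storage and a
# Table-style aggregation of the metrics.

mcmc_profiles <- list(
  full = list(npb = c(25000, 25000), profile = c(25000, 25000),
              bkmr = c(25000, 25000)),
  test = list(npb = c(2500, 2500), profile = c(2500, 2500),
              bkmr = c(1000, 1000))
)

method_ids <- c("lm", "lmint", "npbr", "npb", "upr", "spr", "bkmr")

#' Study configuration for the simulation benchmark
#'
#' @param n subjects per dataset (default 153).
#' @param scenarios subset of "linear", "nonlinear", "profiles", "null",
#'   "complex".
#' @param methods subset of "lm", "lmint", "npbr", "npb", "upr", "spr",
#'   "bkmr".
#' @param n_datasets replicates per scenario (benchmark default 200).
#' @param mcmc "full" (25,000 + 25,000) or "test" (2,500 + 2,500 for the
#'   DP-based methods, 1,000 + 1,000 for the kernel machine), or a list in
#'   the same shape as those profiles.
#' @param master_seed integer master seed; every replicate and method draws
#'   its stream from it via [derive_seed()].
#' @param spec exposure [correlation_spec()] (default [faces_spec()]; the
#'   complex scenario internally doubles it via [complex_spec()]).
#' @param q_cont,q_bin,miss_frac covariate-block shape.
#' @param out_dir optional directory for incremental records (enables
#'   resuming an interrupted study).
#' @return A `study_config`.
#' @export
study_config <- function(n = 153, scenarios = c("linear", "nonlinear", "profiles"),
                         methods = method_ids, n_datasets = 200,
                         mcmc = "full", master_seed = 1, spec = NULL,
                         q_cont = 2, q_bin = 8, miss_frac = 0.05,
                         out_dir = NULL) {
  scenarios <- match.arg(scenarios, scenario_ids, several.ok = TRUE)
  methods <- match.arg(methods, method_ids, several.ok = TRUE)
  if (n_datasets < 1) stop("n_datasets must be at least 1")
  prof <- if (is.character(mcmc)) {
    mcmc_profiles[[match.arg(mcmc, names(mcmc_profiles))]]
  } else {
    mcmc
  }
  structure(list(n = n, scenarios = scenarios, methods = methods,
                 n_datasets = n_datasets, mcmc = prof,
                 master_seed = master_seed, spec = spec,
                 q_cont = q_cont, q_bin = q_bin, miss_frac = miss_frac,
                 out_dir = out_dir),
            class = "study_config")
}

fit_method <- function(id, ds, prof, seed) {
  switch(id,
    lm = fit_lm(ds),
    lmint = fit_lm_int(ds),
    npbr = fit_npbr(ds, n_burn = prof$npb[1], n_keep = prof$npb[2], seed = seed),
    npb = fit_npb(ds, n_burn = prof$npb[1], n_keep = prof$npb[2], seed = seed),
    upr = fit_upr(ds, n_burn = prof$profile[1], n_keep = prof$profile[2], seed = seed),
    spr = fit_spr(ds, n_burn = prof$profile[1], n_keep = prof$profile[2], seed = seed),
    bkmr = fit_bkmr(ds, n_burn = prof$bkmr[1], n_keep = prof$bkmr[2], seed = seed),
    stop("unknown method id: ", id)
  )
}

#' Evaluate one fitted method on one simulated dataset
#'
#' Computes the metric row: RMSE and 95% coverage of h, main-effect TSR/FSR
#' (PIP > 0.5 for the Bayesian fits, CI excluding 0 for least squares), and
#' interaction TSR/FSR for the methods that parameterize interactions (the
#' DP interaction model and LM-int).
#'
#' @param fit a fitted model object.
#' @param ds the `simulated_dataset` it was fit to.
#' @param h_seed seed for stochastic h reconstruction (kernel fits).
#' @return One-row data frame (an EvalRecord).
#' @export
evaluate_fit <- function(fit, ds, h_seed = NULL) {
  est <- if (inherits(fit, "bkmr_fit")) {
    estimate_h(fit, seed = h_seed)
  } else {
    estimate_h(fit)
  }
  sel <- selected_terms(fit)
  sr <- selection_rates(sel$main, ds$active, ds$X$p)
  ir <- if (!is.null(sel$interactions)) {
    interaction_selection_rates(sel$interactions, active_interactions(ds), ds$X$p)
  } else {
    c(tsr_int = NA_real_, fsr_int = NA_real_)
  }
  data.frame(method = fit$method, scenario = ds$scenario_id,
             seed = ds$seed %||% NA_integer_,
             rmse = rmse_h(ds$h_true, est), cvg = coverage_h(ds$h_true, est),
             tsr = unname(sr["tsr"]), fsr = unname(sr["fsr"]),
             tsr_int = unname(ir["tsr_int"]), fsr_int = unname(ir["fsr_int"]),
             error = NA_character_)
}

#' Run the replicated simulation study
#'
#' For each scenario, exposures and covariates are generated once and held
#' fixed across replicates; each replicate re-draws the active components,
#' the covariate coefficients and the noise, then every requested method is
#' fit and evaluated. A failing method yields a record with an error
#' message (excluded from aggregation) rather than aborting the study. With
#' `cfg$out_dir` set, records stream to `records.csv` there and completed
#' (scenario, replicate, method) cells are skipped on restart.
#'
#' @param cfg a [study_config()].
#' @return A `mix_study`: list with `records` (one row per dataset-method)
#'   and `summary` (the aggregated scenario x method table).
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  rec_file <- if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(n = cfg$n, scenarios = cfg$scenarios, methods = cfg$methods,
           n_datasets = cfg$n_datasets, master_seed = cfg$master_seed,
           mcmc = cfg$mcmc,
           package = as.character(utils::packageVersion("mixbench")),
           r_version = R.version.string),
      file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    file.path(cfg$out_dir, "records.csv")
  } else {
    NULL
  }
  done <- if (!is.null(rec_file) && file.exists(rec_file)) {
    old <- utils::read.csv(rec_file)
    records <- split(old, seq_len(nrow(old)))
    sprintf("%s|%d|%s", old$scenario, old$replicate, old$method)
  } else {
    records <- list()
    character(0)
  }

  base_spec <- cfg$spec %||% faces_spec()
  for (sc in cfg$scenarios) {
    spec <- if (sc == "complex") complex_spec(base_spec) else base_spec
    X <- gen_exposures(cfg$n, spec, seed = derive_seed(cfg$master_seed, 1))
    W <- gen_covariates(cfg$n, cfg$q_cont, cfg$q_bin, cfg$miss_frac,
                        seed = derive_seed(cfg$master_seed, 2))
    sc_i <- match(sc, scenario_ids)
    for (r in seq_len(cfg$n_datasets)) {
      ds <- simulate_dataset(X, W, scenario_config(
        sc, seed = derive_seed(cfg$master_seed, sc_i, r)))
      for (m in cfg$methods) {
        key <- sprintf("%s|%d|%s", sc, r, m)
        if (key %in% done) next
        m_i <- match(m, method_ids)
        seed_m <- derive_seed(cfg$master_seed, sc_i, r, m_i)
        row <- tryCatch({
          fit <- fit_method(m, ds, cfg$mcmc, seed_m)
          evaluate_fit(fit, ds, h_seed = derive_seed(seed_m, 7))
        }, error = function(err) {
          data.frame(method = m, scenario = sc, seed = ds$seed,
                     rmse = NA_real_, cvg = NA_real_, tsr = NA_real_,
                     fsr = NA_real_, tsr_int = NA_real_, fsr_int = NA_real_,
                     error = conditionMessage(err))
        })
        row$replicate <- r
        records[[length(records) + 1]] <- row
        if (!is.null(rec_file)) {
          utils::write.table(row, rec_file, sep = ",", row.names = FALSE,
                             col.names = !file.exists(rec_file), append = file.exists(rec_file))
        }
      }
    }
  }
  records <- do.call(rbind, records)
  n_failed <- sum(!is.na(records$error))
  if (n_failed > 0) {
    message(n_failed, " method run(s) failed and were excluded from aggregation")
  }
  structure(list(records = records, summary = aggregate_records(records),
                 config = cfg),
            class = "mix_study")
}

#' Aggregate metric records into a scenario x method summary table
#'
#' Means and standard errors of each metric per (scenario, method) cell,
#' mirroring the shape of a method-comparison table. Failed runs (non-NA
#' `error`) are excluded; interaction columns stay NA for methods that do
#' not parameterize interactions.
#'
#' @param records data frame of rows from [evaluate_fit()].
#' @return Data frame with one row per (scenario, method).
#' @export
aggregate_records <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no records to aggregate")
  ok <- records[is.na(records$error), , drop = FALSE]
  if (nrow(ok) == 0) stop("all records failed; nothing to aggregate")
  metrics <- c("rmse", "cvg", "tsr", "fsr", "tsr_int", "fsr_int")
  cells <- unique(ok[, c("scenario", "method")])
  cells <- cells[order(match(cells$scenario, scenario_ids),
                       match(cells$method, method_ids)), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- ok[ok$scenario == cells$scenario[i] & ok$method == cells$method[i], ]
    means <- vapply(metrics, function(m) mean(sub[[m]], na.rm = TRUE), 0)
    ses <- vapply(metrics, function(m) {
      v <- sub[[m]][!is.na(sub[[m]])]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, 0)
    cbind(data.frame(scenario = cells$scenario[i], method = cells$method[i],
                     n_datasets = nrow(sub)),
          as.data.frame(as.list(means)),
          stats::setNames(as.data.frame(as.list(ses)), paste0(metrics, "_se")))
  }))
  out[vapply(out, is.numeric, TRUE)] <- lapply(
    out[vapply(out, is.numeric, TRUE)], function(x) ifelse(is.nan(x), NA, x))
  rownames(out) <- NULL
  out
}

#' @export
print.mix_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d records (%d scenario(s) x %d method(s))\n",
              nrow(x$records), length(unique(x$records$scenario)),
              length(unique(x$records$method))))
  cols <- c("scenario", "method", "n_datasets", "rmse", "cvg", "tsr", "fsr",
            "tsr_int", "fsr_int")
  tab <- x$summary[, cols]
  tab[, -(1:3)] <- round(tab[, -(1:3)], 2)
  print(tab)
  invisible(x)
}
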