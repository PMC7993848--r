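# Least-squares baselines: main-effects-only (LM) and all pairwise
# interactions (LM-int), with classical t-based intervals, CI-based term
# selection and delta-method confidence bands for the exposure-response
# part of the fit.

fit_linear <- function(ds, interactions) {
  X <- ds$X$values
  if (interactions) {
    int <- interaction_design(X)
    D <- cbind(X, int$Z)
    pairs <- int$pairs
  } else {
    D <- X
    pairs <- matrix(integer(0), 0, 2)
  }
  W <- ds$W$values
  df <- data.frame(y = ds$y, D, W, check.names = FALSE)
  n_par <- 1 + ncol(D) + ncol(W)
  if (length(ds$y) <= n_par) stop("need n greater than the number of parameters")
  fit <- stats::lm(y ~ ., data = df)
  if (fit$rank < n_par) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(lm = fit, exposure_terms = colnames(D), pairs = pairs,
         exposure_names = colnames(X), p = ncol(X),
         interactions = interactions, design = D,
         method = if (interactions) "lmint" else "lm"),
    class = "mix_lm_fit"
  )
}

#' Least-squares baseline with main effects only (LM)
#'
#' Ordinary least squares of the outcome on the standardized exposures,
#' the covariates and an intercept, with classical t-based confidence
#' intervals and p-values.
#'
#' @param ds a `simulated_dataset`.
#' @return An object of class `mix_lm_fit` wrapping the [stats::lm()] fit
#'   together with the exposure-block metadata.
#' @export
fit_lm <- function(ds) fit_linear(ds, interactions = FALSE)

#' Least-squares baseline with all pairwise interactions (LM-int)
#'
#' As [fit_lm()], adding all `p (p - 1) / 2` pairwise exposure products.
#' @inheritParams fit_lm
#' @return A `mix_lm_fit`.
#' @export
fit_lm_int <- function(ds) fit_linear(ds, interactions = TRUE)

#' @export
print.mix_lm_fit <- function(x, ...) {
  cat(sprintf("%s least-squares fit: %d exposure terms + covariates\n",
              toupper(x$method), length(x$exposure_terms)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.mix_lm_fit <- function(object, ...) {
  sm <- summary(object$lm)$coefficients
  ci <- stats::confint(object$lm, level = 0.95)
  keep <- object$exposure_terms
  # lm backtick-protects non-syntactic names; match on the cleaned rownames
  rn <- gsub("`", "", rownames(sm))
  idx <- match(keep, rn)
  data.frame(term = keep, estimate = sm[idx, 1],
             lo = ci[idx, 1], hi = ci[idx, 2], p = sm[idx, 4],
             row.names = NULL)
}

#' @export
coef.mix_lm_fit <- function(object, ...) {
  cf <- stats::coef(object$lm)
  names(cf) <- gsub("`", "", names(cf))
  cf
}

# closed-interval selection rule: an endpoint exactly at 0 keeps 0 inside
ci_excludes_zero <- function(lo, hi) lo > 0 | hi < 0

#' @export
selected_terms.mix_lm_fit <- function(object, ...) {
  sm <- summary(object)
  sel <- ci_excludes_zero(sm$lo, sm$hi)
  main_sel <- which(sel[seq_len(object$p)])
  int_sel <- if (object$interactions) {
    object$pairs[sel[-seq_len(object$p)], , drop = FALSE]
  } else {
    NULL
  }
  list(main = main_sel, interactions = int_sel)
}

#' @rdname estimate_h
#' @export
estimate_h.mix_lm_fit <- function(object, X = NULL, center = TRUE, ...) {
  D <- if (is.null(X)) {
    object$design
  } else {
    Xv <- if (inherits(X, "exposure_table")) X$values else as.matrix(X)
    if (object$interactions) cbind(Xv, interaction_design(Xv)$Z) else Xv
  }
  cf <- coef(object)
  V <- stats::vcov(object$lm)
  rn <- gsub("`", "", rownames(V))
  idx <- match(object$exposure_terms, rn)
  b <- cf[match(object$exposure_terms, names(cf))]
  Vb <- V[idx, idx]
  Cb <- if (center) sweep(D, 2, colMeans(object$design)) else D
  h <- drop(Cb %*% b)
  se <- sqrt(rowSums((Cb %*% Vb) * Cb))
  tq <- stats::qt(0.975, stats::df.residual(object$lm))
  est <- h_estimate(h, h - tq * se, h + tq * se, center = FALSE)
  est$centered <- center
  est
}
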