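# Bayesian profile regression: truncated stick-breaking DP mixture over
# exposure profiles with a per-cluster health effect, in supervised (labels
# see the outcome) and unsupervised / cut-feedback (labels see exposures
# only) forms, plus Dahl's best-partition summary and clustering-based
# variable selection.

#' Prior and truncation settings for profile regression
#'
#' @param C maximum number of clusters (stick-breaking truncation).
#' @param nu0,Lambda0 normal prior on cluster means mu_c ~ N(nu0, Lambda0);
#'   defaults 0 and the identity (unit-scale standardized exposures).
#' @param R0,r0 Wishart prior on cluster precisions Sigma_c^-1 ~
#'   Wishart(R0, r0); defaults I/p and p + 2 (set when the fit sees the
#'   data if left NULL).
#' @param a_alpha,b_alpha Gamma prior on the DP concentration.
#' @param s_theta2 variance of the N(0, s_theta2) prior on cluster health
#'   effects theta_c.
#' @param gamma_var,a_sig,b_sig covariate-coefficient and error-precision
#'   priors, as in [npb_priors()].
#' @param varsel enable per-exposure binary selection switches (the
#'   cluster-specific-versus-common-mean formulation) with a Beta(1,1)
#'   hyperprior on the switch probability.
#' @return A `dpmm_config` list for [fit_spr()] / [fit_upr()].
#' @export
dpmm_config <- function(C = 20, nu0 = NULL, Lambda0 = NULL, R0 = NULL,
                        r0 = NULL, a_alpha = 1, b_alpha = 1, s_theta2 = 10,
                        gamma_var = 100, a_sig = 0.1, b_sig = 0.1,
                        varsel = TRUE) {
  if (C < 2) stop("C must be at least 2")
  structure(list(C = C, nu0 = nu0, Lambda0 = Lambda0, R0 = R0, r0 = r0,
                 a_alpha = a_alpha, b_alpha = b_alpha, s_theta2 = s_theta2,
                 gamma_var = gamma_var, a_sig = a_sig, b_sig = b_sig,
                 varsel = varsel),
            class = "dpmm_config")
}

fit_profile <- function(ds, cfg, n_burn, n_keep, thin, seed, supervised) {
  stopifnot(inherits(cfg, "dpmm_config"))
  X <- ds$X$values
  y <- ds$y
  W <- cbind(`(Intercept)` = 1, ds$W$values)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need at least 10 observations")
  pri <- list(
    nu0 = cfg$nu0 %||% rep(0, p),
    Lambda0 = cfg$Lambda0 %||% diag(p),
    R0 = cfg$R0 %||% (diag(p) / p),
    r0 = cfg$r0 %||% (p + 2),
    a_alpha = cfg$a_alpha, b_alpha = cfg$b_alpha,
    s_theta2 = cfg$s_theta2, gamma_var = cfg$gamma_var,
    a_sig = cfg$a_sig, b_sig = cfg$b_sig
  )
  if (pri$r0 < p) stop("Wishart degrees of freedom r0 must be >= p")
  res <- with_seed(seed, function() {
    profile_mcmc_cpp(X, y, W, cfg$C, supervised, cfg$varsel, pri,
                     n_burn, n_keep, thin)
  })
  if (res$ridge_repairs > 0) {
    warning(sprintf("%d singular cluster covariance draw(s) repaired with a 1e-8 ridge",
                    res$ridge_repairs))
  }
  colnames(res$g) <- colnames(X)
  structure(
    list(z = res$z, theta = res$theta, g = res$g, gamma = res$gamma,
         sigma2 = res$sigma2, alpha = res$alpha,
         n_occupied = res$n_occupied,
         mode = if (supervised) "supervised" else "unsupervised",
         varsel = cfg$varsel, C = cfg$C, exposure_names = colnames(X),
         n = n, p = p, n_burn = n_burn, n_keep = n_keep, thin = thin,
         seed = seed, cfg = cfg,
         method = if (supervised) "spr" else "upr"),
    class = "profile_fit"
  )
}

#' Fit supervised Bayesian profile regression (SPR)
#'
#' Blocked Gibbs sampler on the truncated stick-breaking representation:
#' cluster labels are drawn from the product of the exposure likelihood
#' N(x_i | mu_c, Sigma_c) and the response likelihood
#' N(y_i | theta_c + w_i'gamma, sigma^2), so the outcome feeds back into
#' the clustering.
#'
#' @param ds a `simulated_dataset`.
#' @param cfg a [dpmm_config()].
#' @param n_burn,n_keep,thin chain control.
#' @param seed integer seed.
#' @return An object of class `profile_fit` holding per-iteration labels,
#'   cluster effects, selection switches and variance draws.
#' @seealso [fit_upr()], [dahl_best_partition()], [vs_pips()]
#' @export
fit_spr <- function(ds, cfg = dpmm_config(), n_burn = 25000, n_keep = 25000,
                    thin = 1, seed = NULL) {
  fit_profile(ds, cfg, n_burn, n_keep, thin, seed, supervised = TRUE)
}

#' Fit unsupervised Bayesian profile regression (UPR)
#'
#' Identical sampler except the label update is cut from the response: z_i
#' depends only on the exposure likelihood, so the clustering marginals are
#' those of an exposures-only DP mixture while the cluster health effects
#' theta_c are still refreshed given current memberships (one cut-feedback
#' chain, which propagates clustering uncertainty into theta).
#'
#' @inheritParams fit_spr
#' @return A `profile_fit`.
#' @export
fit_upr <- function(ds, cfg = dpmm_config(), n_burn = 25000, n_keep = 25000,
                    thin = 1, seed = NULL) {
  fit_profile(ds, cfg, n_burn, n_keep, thin, seed, supervised = FALSE)
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("%s profile regression: %d kept draws, truncation C = %d\n",
              toupper(x$method), nrow(x$z), x$C))
  cat(sprintf("  occupied clusters (posterior mode): %d\n",
              as.integer(names(which.max(table(x$n_occupied))))))
  if (x$varsel) {
    cat("  selection PIPs:\n")
    print(round(pips(x), 3))
  }
  invisible(x)
}

#' Stick-breaking weights
#'
#' Maps stick fractions `V` (with the last element 1 under truncation) to
#' mixture weights `psi_c = V_c * prod_{h<c} (1 - V_h)`; the weights sum to
#' one exactly by telescoping.
#'
#' @param V numeric vector in `[0, 1]`, last element 1.
#' @return Numeric vector of weights summing to 1.
#' @export
stick_breaking_weights <- function(V) {
  if (any(V < 0 | V > 1)) stop("stick fractions must lie in [0, 1]")
  if (utils::tail(V, 1) != 1) stop("last stick fraction must be 1 under truncation")
  c(V) * cumprod(c(1, 1 - utils::head(V, -1)))
}

canonical_labels <- function(z) {
  # renumber clusters by first appearance so partitions compare by shape
  match(z, unique(z))
}

#' Dahl's best-partition summary of a clustering posterior
#'
#' Builds the co-membership probability matrix `S` (the average over
#' retained iterations of the n x n same-cluster score matrices) and
#' returns the iteration whose score matrix has minimum squared distance
#' to `S` (earliest iteration on ties), with labels in canonical
#' first-appearance order.
#'
#' @param post a `profile_fit` (or an integer matrix of labels, iterations
#'   in rows).
#' @return A list of class `dahl_partition`: `labels` (canonical), `S`,
#'   `iteration` (index of the chosen draw), `distance`.
#' @export
dahl_best_partition <- function(post) {
  z <- if (inherits(post, "profile_fit")) post$z else as.matrix(post)
  if (nrow(z) < 1) stop("need at least one retained iteration")
  res <- dahl_scores_cpp(z)
  structure(
    list(labels = canonical_labels(z[res$best, ]), S = res$S,
         iteration = res$best, distance = res$dist[res$best]),
    class = "dahl_partition"
  )
}

#' @export
print.dahl_partition <- function(x, ...) {
  cat(sprintf("Dahl best partition: %d clusters over %d subjects (iteration %d, distance %.3f)\n",
              length(unique(x$labels)), length(x$labels), x$iteration, x$distance))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Model-averaged cluster effects for a best partition
#'
#' For each cluster of the best partition, the distribution over retained
#' iterations of the average current health effect of its members
#' (mean over i in the cluster of theta_{z_i(t)} at iteration t), which
#' propagates clustering uncertainty into the cluster-effect summary. Also
#' returns the per-iteration overall mean effect across all subjects.
#'
#' @param post a `profile_fit`.
#' @param best a `dahl_partition` from the same posterior.
#' @return List with `draws` (iterations x clusters matrix), `overall`
#'   (per-iteration overall mean), `means` and 95% quantile bounds.
#' @export
model_averaged_theta <- function(post, best) {
  stopifnot(inherits(post, "profile_fit"), inherits(best, "dahl_partition"))
  groups <- sort(unique(best$labels))
  Tn <- nrow(post$z)
  H <- matrix(post$theta[cbind(rep(seq_len(Tn), post$n),
                               as.vector(post$z))], Tn, post$n)
  draws <- vapply(groups, function(g) {
    rowMeans(H[, best$labels == g, drop = FALSE])
  }, numeric(Tn))
  if (!is.matrix(draws)) draws <- matrix(draws, nrow = Tn)
  colnames(draws) <- paste0("cluster", groups)
  list(draws = draws, overall = rowMeans(H),
       means = colMeans(draws),
       lo = apply(draws, 2, stats::quantile, 0.025),
       hi = apply(draws, 2, stats::quantile, 0.975))
}

#' Clustering-based variable selection PIPs
#'
#' Posterior fraction of retained iterations in which an exposure's
#' cluster-specific-mean switch is on, i.e. the exposure is informative for
#' partitioning the profiles (not necessarily associated with the outcome).
#'
#' @param post a `profile_fit` run with `varsel = TRUE`.
#' @return Named numeric vector of per-exposure PIPs.
#' @export
vs_pips <- function(post) {
  stopifnot(inherits(post, "profile_fit"))
  if (!post$varsel) {
    stop("variable selection was disabled in this fit; rerun with dpmm_config(varsel = TRUE)")
  }
  colMeans(post$g)
}

#' @export
pips.profile_fit <- function(object, ...) vs_pips(object)

#' @export
selected_terms.profile_fit <- function(object, threshold = 0.5, ...) {
  list(main = which(unname(pips(object)) > threshold),
       interactions = NULL)
}

#' @rdname estimate_h
#' @export
estimate_h.profile_fit <- function(object, center = TRUE, ...) {
  Tn <- nrow(object$z)
  H <- matrix(object$theta[cbind(rep(seq_len(Tn), object$n),
                                 as.vector(object$z))], Tn, object$n)
  h_estimate(colMeans(H),
             apply(H, 2, stats::quantile, 0.025),
             apply(H, 2, stats::quantile, 0.975),
             center = center)
}

#' @export
coef.profile_fit <- function(object, ...) {
  best <- dahl_best_partition(object)
  model_averaged_theta(object, best)$means
}
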