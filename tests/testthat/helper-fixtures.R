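# Shared fixtures: cached specs and small synthetic datasets built in code.

cached_spec <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- faces_spec()
    s
  }
})

# Minimal hand-built dataset wrapper for unit tests that need full control
# over y / h_true / active.
manual_ds <- function(y, X, W, active = integer(0), h_true = rep(0, length(y)),
                      gamma = rep(0, W$q), scenario = "linear", seed = 1) {
  structure(
    list(y = y, X = X, W = W, active = as.integer(active), h_true = h_true,
         gamma = gamma, scenario_id = scenario, noise_sd = 1, seed = seed),
    class = "simulated_dataset"
  )
}

# Small standardized exposure table from |N(0,1)| draws
toy_exposures <- function(n, p = 3, seed = 1) {
  set.seed(seed)
  raw <- matrix(abs(stats::rnorm(n * p)), n, p,
                dimnames = list(NULL, paste0("e", seq_len(p))))
  standardize_exposures(raw)
}

toy_covariates <- function(n, seed = 2) {
  gen_covariates(n, q_cont = 1, q_bin = 1, miss_frac = 0, seed = seed)
}

# Exposure table around two well-separated blobs (for clustering tests)
blob_exposures <- function(n_per = 50, p = 3, centers = c(-2, 2), seed = 1) {
  set.seed(seed)
  raw <- rbind(matrix(stats::rnorm(n_per * p, centers[1]), n_per, p),
               matrix(stats::rnorm(n_per * p, centers[2]), n_per, p))
  colnames(raw) <- paste0("e", seq_len(p))
  tab <- mixbench:::new_exposure_table(scale(raw))
  tab
}

# Brute-force posterior over the 5 zero/cluster configurations of a
# two-coefficient DP point-mass shrinkage model with all hyperparameters
# fixed (intercept integrated out analytically). Used as the exact oracle
# for the sampler.
enumerate_npb_configs <- function(y, x1, x2, alpha, pi0, mu, phi2, sigma2,
                                  gvar) {
  n <- length(y)
  base <- diag(sigma2, n) + gvar * matrix(1, n, n)
  dens <- function(mean, cov) mvtnorm::dmvnorm(y, mean, cov)
  lik <- c(
    zz = dens(rep(0, n), base),
    z2 = dens(x2 * mu, base + phi2 * tcrossprod(x2)),
    `1z` = dens(x1 * mu, base + phi2 * tcrossprod(x1)),
    shared = dens((x1 + x2) * mu, base + phi2 * tcrossprod(x1 + x2)),
    separate = dens((x1 + x2) * mu,
                    base + phi2 * (tcrossprod(x1) + tcrossprod(x2)))
  )
  # sequential (Polya-urn) prior mass of each configuration
  prior <- c(
    zz = pi0 * (1 + alpha * pi0) / (1 + alpha),
    z2 = pi0 * alpha * (1 - pi0) / (1 + alpha),
    `1z` = (1 - pi0) * alpha * pi0 / (1 + alpha),
    shared = (1 - pi0) / (1 + alpha),
    separate = (1 - pi0) * alpha * (1 - pi0) / (1 + alpha)
  )
  post <- prior * lik
  post / sum(post)
}

classify_draws <- function(fit) {
  l1 <- fit$labels[, 1]; l2 <- fit$labels[, 2]
  ifelse(l1 < 0 & l2 < 0, "zz",
    ifelse(l1 < 0, "z2",
      ifelse(l2 < 0, "1z", ifelse(l1 == l2, "shared", "separate"))))
}

adjusted_rand <- function(a, b) {
  # Hubert-Arabie adjusted Rand index
  tab <- table(a, b)
  sn <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  exp_idx <- sa * sb / n2
  (sn - exp_idx) / ((sa + sb) / 2 - exp_idx)
}
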