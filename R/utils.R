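# Internal helpers: seed plumbing, log-sum-exp, Gauss-Hermite nodes.

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer stream
#' identifiers (replicate index, method index, ...) into a new seed in
#' `[1, 2^31 - 2]`. Used by the simulation harness so that every replicate
#' and method gets its own reproducible RNG stream.
#'
#' @param master integer master seed.
#' @param ... further integer identifiers (replicate index, method id, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- as.numeric(master) %% m
  for (k in c(...)) {
    s <- (s * 48271 + (as.numeric(k) %% m) * 69621 + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate fn() under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  fn()
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch on the Legendre
# recurrence); rescale_gl maps them to an arbitrary interval [a, b].
gauss_legendre <- function(k) {
  i <- seq_len(k - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

rescale_gl <- function(gl, a, b) {
  list(nodes = (a + b) / 2 + (b - a) / 2 * gl$nodes,
       weights = (b - a) / 2 * gl$weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
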