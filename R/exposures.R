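# Synthetic exposure generation: Gaussian copula over right-skewed marginals,
# calibrated so the generated matrix reproduces a target Spearman correlation
# structure, followed by the square-root / z-score preprocessing convention.

#' Correlation specification for the exposure simulator
#'
#' Bundles the exposure labels, the target matrix of pairwise Spearman rank
#' correlations, and the per-exposure marginal distributions (lognormal, with
#' an optional point mass at zero for exposures that are absent for many
#' subjects, e.g. localized pesticide applications). At construction time the
#' latent Gaussian-copula correlation needed to attain each target Spearman
#' correlation is solved and cached:
#' \itemize{
#'   \item for two continuous marginals the classical exact map
#'     \eqn{2 \sin(\pi \rho / 6)} is used;
#'   \item when either marginal has a point mass at zero, ties attenuate the
#'     midrank Spearman correlation, so the latent correlation is found by
#'     numerically inverting the midrank-Spearman functional of the copula
#'     (two-dimensional Gauss-Hermite quadrature + root finding).
#' }
#' The assembled latent matrix is repaired to the nearest positive
#' semi-definite matrix (eigenvalue clipping at 1e-8, rescaled to unit
#' diagonal) if required.
#'
#' @param names character vector of exposure labels.
#' @param rho symmetric matrix of target Spearman correlations with unit
#'   diagonal, entries in `[-1, 1]`.
#' @param marginals list (one element per exposure) with components
#'   `mean`, `sd` (marginal mean/SD on the concentration scale) and
#'   `zero_mass` (probability of an exact zero; 0 for fully continuous).
#' @return An object of class `corr_spec`.
#' @seealso [faces_spec()], [gen_exposures()]
#' @export
correlation_spec <- function(names, rho, marginals) {
  p <- length(names)
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == p, ncol(rho) == p)
  if (max(abs(rho - t(rho))) > 1e-10) stop("rho must be symmetric")
  if (any(abs(diag(rho) - 1) > 1e-10)) stop("rho must have unit diagonal")
  if (any(rho < -1 | rho > 1)) stop("rho entries must lie in [-1, 1]")
  if (length(marginals) != p) stop("need one marginal per exposure")
  marginals <- lapply(marginals, function(m) {
    m$zero_mass <- m$zero_mass %||% 0
    if (m$zero_mass < 0 || m$zero_mass >= 1) stop("zero_mass must be in [0, 1)")
    body <- lognormal_body(m$mean, m$sd, m$zero_mass)
    c(m, body)
  })
  names(marginals) <- names
  lat <- latent_correlation(rho, vapply(marginals, `[[`, 0, "zero_mass"))
  structure(
    list(names = names, p = p, rho = rho, marginals = marginals,
         latent = lat$latent, repaired = lat$repaired),
    class = "corr_spec"
  )
}

# Moment-match the lognormal body of a (possibly zero-inflated) marginal so
# the overall mean/SD equal the printed summary statistics.
lognormal_body <- function(mean, sd, p0) {
  stopifnot(mean > 0, sd > 0)
  mb <- mean / (1 - p0)
  eb2 <- (sd^2 + mean^2) / (1 - p0)
  vb <- eb2 - mb^2
  if (vb <= 0) {
    stop("marginal mean/SD/zero-mass combination implies non-positive body variance")
  }
  s2 <- log(1 + vb / mb^2)
  list(meanlog = log(mb) - s2 / 2, sdlog = sqrt(s2))
}

# Population midrank Spearman correlation attained by a Gaussian copula with
# latent correlation `rl` over two marginals with zero masses p0x, p0y.
#
# The midrank grade of a zero-inflated marginal is h(z) = p0/2 for latent
# scores below the zero threshold (all zeros share one midrank) and Phi(z)
# above it. Its mean is 1/2 and its variance p0^3/4 + (1-p0^3)/3 - 1/4 in
# closed form. The cross moment E[h_x(Z1) h_y(Z2)] is integrated with
# Gauss-Legendre rules split exactly at the thresholds, where the grade
# functions jump, so every panel integrand is smooth.
spearman_attained <- function(rl, p0x, p0y, gl) {
  s <- sqrt(max(1e-12, 1 - rl^2))
  tx <- if (p0x > 0) stats::qnorm(p0x) else -8
  ty <- if (p0y > 0) stats::qnorm(p0y) else -8
  lim <- 8
  inner <- function(z) {
    # E[h_y(rl*z + s*V)], V ~ N(0,1), for a vector of outer nodes z
    vstar <- pmin(pmax((ty - rl * z) / s, -lim), lim)
    base <- (p0y / 2) * stats::pnorm(vstar)
    tail <- vapply(seq_along(z), function(i) {
      giv <- rescale_gl(gl, vstar[i], lim)
      sum(giv$weights * stats::pnorm(rl * z[i] + s * giv$nodes) *
            stats::dnorm(giv$nodes))
    }, 0)
    base + tail
  }
  g_lo <- rescale_gl(gl, -lim, tx)   # h_x constant at p0x/2
  g_hi <- rescale_gl(gl, tx, lim)    # h_x = Phi(z)
  e <- (p0x / 2) * sum(g_lo$weights * stats::dnorm(g_lo$nodes) * inner(g_lo$nodes)) +
    sum(g_hi$weights * stats::dnorm(g_hi$nodes) * stats::pnorm(g_hi$nodes) *
          inner(g_hi$nodes))
  grade_var <- function(p0) p0^3 / 4 + (1 - p0^3) / 3 - 0.25
  (e - 0.25) / sqrt(grade_var(p0x) * grade_var(p0y))
}

# Solve for the latent Pearson correlation reproducing each target Spearman
# entry; exact 2*sin(pi*rho/6) where both marginals are continuous.
latent_correlation <- function(rho, p0) {
  p <- nrow(rho)
  lat <- diag(p)
  gl <- gauss_legendre(60)
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      target <- rho[j, k]
      if (target == 0) {
        r <- 0
      } else if (p0[j] == 0 && p0[k] == 0) {
        r <- 2 * sin(pi * target / 6)
      } else {
        f <- function(rl) spearman_attained(rl, p0[j], p0[k], gl) - target
        lo <- -0.999; hi <- 0.999
        if (f(lo) > 0 || f(hi) < 0) {
          stop(sprintf("target Spearman %.2f between %d and %d is unattainable under the tied marginals",
                       target, j, k))
        }
        r <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
      }
      lat[j, k] <- lat[k, j] <- r
    }
  }
  repaired <- FALSE
  e <- eigen(lat, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    v <- pmax(e$values, 1e-8)
    lat <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(lat))
    lat <- lat / tcrossprod(d)
    repaired <- TRUE
    if (min(eigen(lat, symmetric = TRUE)$values) < 0) {
      stop("latent correlation matrix is not positive semi-definite after repair; ",
           "check the target Spearman matrix for internal inconsistency")
    }
  }
  list(latent = lat, repaired = repaired)
}

#' Built-in exposure specification from published cohort summaries
#'
#' Reads the bundled JSON file encoding the printed marginal summary
#' statistics (mean, SD, quartiles) and the Spearman correlation matrix of
#' the seven-exposure air-pollution/pesticide mixture (carbamates, methyl
#' bromide, organophosphates, O3, NO2, PM2.5, PM10), and builds the
#' corresponding [correlation_spec()]. Pesticide classes with printed
#' medians (and for methyl bromide even the 75th percentile) equal to zero
#' are modelled as zero-inflated lognormal; air pollutants as lognormal
#' moment-matched to the printed mean/SD.
#'
#' @param file path to the summary JSON; defaults to the bundled file.
#' @return A `corr_spec` for the 7 exposures.
#' @export
faces_spec <- function(file = system.file("extdata", "faces_summary.json",
                                          package = "mixbench")) {
  js <- jsonlite::fromJSON(file)
  nm <- js$exposures
  p <- length(nm)
  rho <- diag(p)
  dimnames(rho) <- list(nm, nm)
  for (a in names(js$spearman$upper)) {
    for (b in names(js$spearman$upper[[a]])) {
      rho[a, b] <- rho[b, a] <- js$spearman$upper[[a]][[b]]
    }
  }
  marg <- lapply(nm, function(x) {
    list(mean = js$marginals[[x]]$mean, sd = js$marginals[[x]]$sd,
         zero_mass = js$zero_mass[[x]])
  })
  correlation_spec(nm, rho, marg)
}

#' Doubled 14-exposure specification for the complex-mixture scenario
#'
#' Duplicates a 7-exposure block into a 14-component mixture: the second
#' block repeats the marginals and within-block correlation of the first,
#' and every across-block pair is assigned a common weak Spearman
#' correlation (default 0.2). Used by the high-dimensional outcome scenario.
#'
#' @param base a `corr_spec` to duplicate (default [faces_spec()]).
#' @param between across-block Spearman correlation.
#' @return A `corr_spec` for `2 * base$p` exposures.
#' @export
complex_spec <- function(base = faces_spec(), between = 0.2) {
  p <- base$p
  nm <- c(base$names, paste0(base$names, "_b"))
  B <- matrix(between, p, p)
  rho <- rbind(cbind(base$rho, B), cbind(B, base$rho))
  diag(rho) <- 1
  marg <- lapply(base$marginals, function(m) m[c("mean", "sd", "zero_mass")])
  correlation_spec(nm, rho, c(marg, marg))
}

#' Generate a synthetic standardized exposure matrix
#'
#' Draws `n` exposure profiles from a Gaussian copula with the calibrated
#' latent correlation of `spec`, pushes the uniform grades through each
#' marginal's quantile function (zeros below the zero mass, lognormal body
#' above), and applies the square-root / z-score preprocessing via
#' [standardize_exposures()]. Deterministic given `seed`.
#'
#' @param n number of profiles (rows), at least 2.
#' @param spec a [correlation_spec()].
#' @param seed integer seed (optional; the caller's RNG state is restored).
#' @return An `exposure_table`: list with `values` (n x p standardized
#'   matrix), `names`, `n`, `p`, and provenance attributes.
#' @examples
#' spec <- faces_spec()
#' x <- gen_exposures(500, spec, seed = 1)
#' round(stats::cor(x$values[, "NO2"], x$values[, "PM25"], method = "spearman"), 2)
#' @export
gen_exposures <- function(n, spec, seed = NULL) {
  stopifnot(inherits(spec, "corr_spec"))
  if (n < 2) stop("n must be at least 2")
  with_seed(seed, function() {
    L <- chol(spec$latent + diag(1e-10, spec$p))
    Z <- matrix(stats::rnorm(n * spec$p), n, spec$p) %*% L
    U <- stats::pnorm(Z)
    raw <- vapply(seq_len(spec$p), function(j) {
      m <- spec$marginals[[j]]
      out <- numeric(n)
      body <- U[, j] > m$zero_mass
      out[body] <- stats::qlnorm((U[body, j] - m$zero_mass) / (1 - m$zero_mass),
                                 m$meanlog, m$sdlog)
      out
    }, numeric(n))
    colnames(raw) <- spec$names
    tab <- standardize_exposures(raw)
    tab$provenance <- "synthetic"
    tab$seed <- seed
    tab
  })
}

#' Square-root transform and standardize a nonnegative exposure matrix
#'
#' Applies the preprocessing convention for right-skewed exposures:
#' elementwise square root, then a per-column z-score using the sample mean
#' and SD of the same matrix (within-sample scaling; no external reference).
#'
#' @param raw n x p matrix (or `exposure_table`) of nonnegative exposures.
#' @return An `exposure_table` whose columns have mean 0 and SD 1.
#' @export
standardize_exposures <- function(raw) {
  if (inherits(raw, "exposure_table")) raw <- raw$values
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("exposure matrix must be numeric")
  if (anyNA(raw)) stop("exposure matrix must not contain missing values")
  if (any(raw < 0)) stop("exposure matrix must be nonnegative (found negative entries)")
  s <- sqrt(raw)
  mu <- colMeans(s)
  sd <- apply(s, 2, stats::sd)
  zero <- which(sd == 0 | !is.finite(sd))
  if (length(zero)) {
    nm <- colnames(s)[zero] %||% as.character(zero)
    stop("zero-variance exposure column(s): ", paste(nm, collapse = ", "))
  }
  v <- sweep(sweep(s, 2, mu), 2, sd, "/")
  new_exposure_table(v, provenance = "standardized")
}

new_exposure_table <- function(values, provenance = "loaded") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  }
  structure(
    list(values = values, names = colnames(values),
         n = nrow(values), p = ncol(values), provenance = provenance),
    class = "exposure_table"
  )
}

#' @export
print.exposure_table <- function(x, ...) {
  cat(sprintf("Exposure table: %d profiles x %d exposures (%s)\n",
              x$n, x$p, x$provenance))
  cat("  exposures:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Load an exposure matrix from a CSV file
#'
#' Reads a rectangular, numeric, headered CSV and (optionally) routes it
#' through [standardize_exposures()], supporting benchmark runs on a user's
#' own exposure data in place of the synthetic cohort.
#'
#' @param path CSV path (comma-separated, header row).
#' @param standardize apply the square-root/z-score convention (default TRUE).
#' @return An `exposure_table`.
#' @export
load_exposure_csv <- function(path, standardize = TRUE) {
  m <- read_numeric_csv(path)
  if (standardize) {
    tab <- standardize_exposures(m)
    tab$provenance <- paste0("loaded:", path)
    tab
  } else {
    new_exposure_table(m, provenance = paste0("loaded:", path))
  }
}

# Strict rectangular numeric CSV reader with row/column diagnostics.
read_numeric_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("CSV must have a header row and at least one data row: ", path)
  nfield <- lengths(strsplit(lines, ",", fixed = TRUE))
  if (length(unique(nfield)) != 1) {
    bad <- which(nfield != nfield[1])[1]
    stop(sprintf("ragged CSV: row %d has %d fields, header has %d (%s)",
                 bad, nfield[bad], nfield[1], path))
  }
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (anyDuplicated(names(tab))) {
    stop("duplicate column headers: ",
         paste(unique(names(tab)[duplicated(names(tab))]), collapse = ", "))
  }
  m <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(tab)))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at row %d, column '%s' in %s",
                 idx[1], colnames(m)[idx[2]], path))
  }
  m
}
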