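# Covariate block: continuous + binary confounders with occasional
# missingness in the binaries, handled by zero imputation plus
# missing-indicator columns.

new_covariate_table <- function(values, kinds) {
  values <- as.matrix(values)
  stopifnot(length(kinds) == ncol(values))
  structure(
    list(values = values, kinds = kinds, q = ncol(values), n = nrow(values)),
    class = "covariate_table"
  )
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("Covariate table: %d subjects x %d columns (%s)\n", x$n, x$q,
              paste(sprintf("%d %s", table(x$kinds), names(table(x$kinds))),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic covariate matrix
#'
#' Emulates a typical confounder block for a small respiratory-health cohort:
#' a few standardized continuous covariates (e.g. temperature, precipitation,
#' BMI) and several binary indicators (smoking in the home, atopy, income,
#' ...) with prevalences drawn once per column from U(0.1, 0.6). A fraction
#' of the binary entries can be masked as missing and is then routed through
#' [impute_missing_binary()], appending one missing-indicator column per
#' affected binary.
#'
#' @param n subjects.
#' @param q_cont number of continuous covariates.
#' @param q_bin number of binary covariates.
#' @param miss_frac per-entry missingness probability for binaries, in
#'   `[0, 0.25]`.
#' @param seed integer seed.
#' @return A `covariate_table` with `q_cont + q_bin` columns plus one
#'   indicator per binary column that had at least one masked entry.
#' @export
gen_covariates <- function(n, q_cont = 2, q_bin = 8, miss_frac = 0.05,
                           seed = NULL) {
  stopifnot(n >= 1, q_cont >= 0, q_bin >= 0)
  if (miss_frac < 0 || miss_frac > 0.25) stop("miss_frac must be in [0, 0.25]")
  with_seed(seed, function() {
    cont <- if (q_cont > 0) {
      matrix(stats::rnorm(n * q_cont), n, q_cont,
             dimnames = list(NULL, paste0("cont", seq_len(q_cont))))
    } else {
      matrix(0, n, 0)
    }
    bin <- if (q_bin > 0) {
      prev <- stats::runif(q_bin, 0.1, 0.6)
      b <- vapply(prev, function(pr) stats::rbinom(n, 1, pr), numeric(n))
      colnames(b) <- paste0("bin", seq_len(q_bin))
      b
    } else {
      matrix(0, n, 0)
    }
    vals <- cbind(cont, bin)
    kinds <- c(rep("continuous", q_cont), rep("binary", q_bin))
    mask <- matrix(FALSE, n, ncol(vals))
    if (q_bin > 0 && miss_frac > 0) {
      mask[, q_cont + seq_len(q_bin)] <-
        matrix(stats::runif(n * q_bin) < miss_frac, n, q_bin)
    }
    impute_missing_binary(vals, mask, kinds = kinds)
  })
}

#' Zero-impute masked binary covariates and append missing indicators
#'
#' Masked entries (allowed only in binary columns) are set to 0 and, for
#' every column with at least one masked entry, a missing-indicator column
#' equal to the mask is appended, preserving the information about which
#' values were imputed.
#'
#' @param values_with_missing n x q numeric matrix (masked entries may hold
#'   any placeholder; they are overwritten with 0).
#' @param mask n x q logical matrix marking missing entries.
#' @param kinds optional per-column kind tags ("continuous"/"binary");
#'   inferred from the observed values when omitted.
#' @return A `covariate_table`.
#' @export
impute_missing_binary <- function(values_with_missing, mask, kinds = NULL) {
  v <- as.matrix(values_with_missing)
  mask <- as.matrix(mask)
  stopifnot(all(dim(v) == dim(mask)))
  q <- ncol(v)
  if (is.null(colnames(v))) colnames(v) <- paste0("w", seq_len(q))
  if (is.null(kinds)) {
    kinds <- vapply(seq_len(q), function(j) {
      obs <- v[!mask[, j], j]
      if (all(obs %in% c(0, 1))) "binary" else "continuous"
    }, "")
  }
  for (j in seq_len(q)) {
    if (any(mask[, j])) {
      if (kinds[j] != "binary") {
        stop("masked entries in non-binary column '", colnames(v)[j], "'")
      }
      obs <- v[!mask[, j], j]
      if (!all(obs %in% c(0, 1))) {
        stop("masked column '", colnames(v)[j], "' has non-binary observed values")
      }
    }
  }
  affected <- which(colSums(mask) > 0)
  v[mask] <- 0
  if (length(affected)) {
    ind <- mask[, affected, drop = FALSE] * 1
    colnames(ind) <- paste0(colnames(v)[affected], "_miss")
    v <- cbind(v, ind)
    kinds <- c(kinds, rep("missing-indicator", length(affected)))
  }
  new_covariate_table(v, kinds)
}

#' Load a covariate matrix from CSV
#'
#' @param path CSV path (numeric, rectangular, header row). Column kinds are
#'   inferred: columns whose values are all 0/1 are tagged binary.
#' @return A `covariate_table`.
#' @export
load_covariate_csv <- function(path) {
  m <- read_numeric_csv(path)
  kinds <- vapply(seq_len(ncol(m)), function(j) {
    if (all(m[, j] %in% c(0, 1))) "binary" else "continuous"
  }, "")
  new_covariate_table(m, kinds)
}
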