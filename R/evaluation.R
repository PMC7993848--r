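# Benchmark metrics: RMSE and pointwise 95% interval coverage of the
# exposure-response function (after the level-free centering convention),
# true/false selection rates for main effects and interactions, and the
# clustering statistics summarizing the grouping structure of the
# fixed-profiles scenario.

center_pair <- function(h_true, est) {
  ht <- h_true - mean(h_true)
  if (!isTRUE(est$centered)) {
    m <- mean(est$mean)
    est$mean <- est$mean - m; est$lo <- est$lo - m; est$hi <- est$hi - m
    est$centered <- TRUE
  }
  list(h = ht, est = est)
}

#' Root mean squared error of an exposure-response estimate
#'
#' `sqrt(mean((h(x_i) - hhat(x_i))^2))` after centering both the true and
#' the estimated function at their own sample means (so a common additive
#' constant does not count as error).
#'
#' @param h_true length-n true exposure-response vector.
#' @param est an `h_estimate` of the same length.
#' @return Nonnegative scalar.
#' @export
rmse_h <- function(h_true, est) {
  if (length(h_true) != length(est$mean)) stop("length mismatch")
  z <- center_pair(h_true, est)
  sqrt(mean((z$h - z$est$mean)^2))
}

#' Pointwise 95% interval coverage of the true exposure-response function
#'
#' Fraction of subjects whose centered true `h(x_i)` lies inside the
#' centered closed interval `[lo_i, hi_i]`.
#'
#' @inheritParams rmse_h
#' @return Proportion in `[0, 1]`.
#' @export
coverage_h <- function(h_true, est) {
  if (length(h_true) != length(est$mean)) stop("length mismatch")
  z <- center_pair(h_true, est)
  mean(z$h >= z$est$lo & z$h <= z$est$hi)
}

#' Main-effect true and false selection rates
#'
#' TSR = |selected ∩ active| / |active|; FSR = |selected \ active| /
#' (p - |active|). With no active components (null scenario) TSR is
#' undefined and reported as NA.
#'
#' @param selected integer indices of selected exposures.
#' @param active integer indices of truly active exposures.
#' @param p total number of exposures.
#' @return Named vector `c(tsr, fsr)`.
#' @export
selection_rates <- function(selected, active, p) {
  selected <- as.integer(selected); active <- as.integer(active)
  if (any(c(selected, active) < 1) || any(c(selected, active) > p)) {
    stop("indices out of range 1..p")
  }
  tsr <- if (length(active) == 0) NA_real_ else {
    length(intersect(selected, active)) / length(active)
  }
  fsr <- if (p == length(active)) NA_real_ else {
    length(setdiff(selected, active)) / (p - length(active))
  }
  c(tsr = tsr, fsr = fsr)
}

pair_key <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) return(character(0))
  apply(t(apply(pairs, 1, sort)), 1, paste, collapse = "-")
}

#' Interaction true and false selection rates
#'
#' As [selection_rates()] but over unordered exposure pairs; the inactive
#' set has `p (p - 1) / 2 - n_active` pairs.
#'
#' @param selected_pairs,active_pairs 2-column matrices of exposure index
#'   pairs (unordered).
#' @param p total number of exposures.
#' @return Named vector `c(tsr_int, fsr_int)`.
#' @export
interaction_selection_rates <- function(selected_pairs, active_pairs, p) {
  if (!is.null(selected_pairs) && nrow(selected_pairs) &&
      (any(selected_pairs < 1) || any(selected_pairs > p))) {
    stop("pair indices out of range 1..p")
  }
  sel <- pair_key(selected_pairs)
  act <- pair_key(active_pairs)
  npairs <- p * (p - 1) / 2
  tsr <- if (length(act) == 0) NA_real_ else length(intersect(sel, act)) / length(act)
  fsr <- if (npairs == length(act)) NA_real_ else {
    length(setdiff(sel, act)) / (npairs - length(act))
  }
  c(tsr_int = tsr, fsr_int = fsr)
}

#' Clustering statistics of a labeled exposure matrix
#'
#' Summarizes how much grouping structure a labeling induces on the
#' standardized exposures: the Calinski-Harabasz pseudo-F index, the mean
#' silhouette width, and a label-free estimate of the number of clusters
#' maximizing the gap statistic (k-means over k = 1..10 against
#' uniform-box reference sets).
#'
#' @param X an `exposure_table` or numeric matrix.
#' @param labels group labels (e.g. the four fixed-profile groups).
#' @param k_max,B gap-statistic search range and number of reference sets.
#' @param seed seed for the gap-statistic reference draws.
#' @return List with `ch`, `silhouette`, `gap_k`. CH and silhouette are NA
#'   when fewer than 2 nonempty groups are present.
#' @export
clustering_stats <- function(X, labels, k_max = 10, B = 50, seed = NULL) {
  Xv <- if (inherits(X, "exposure_table")) X$values else as.matrix(X)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  n <- nrow(Xv)
  if (k >= 2) {
    centers <- rowsum(Xv, labels) / as.vector(table(labels))
    grand <- colMeans(Xv)
    bss <- sum(as.vector(table(labels)) * rowSums(sweep(centers, 2, grand)^2))
    wss <- sum((Xv - centers[labels, , drop = FALSE])^2)
    ch <- (bss / (k - 1)) / (wss / (n - k))
    sil <- mean(cluster::silhouette(labels, stats::dist(Xv))[, "sil_width"])
  } else {
    ch <- NA_real_
    sil <- NA_real_
  }
  gap_k <- with_seed(seed, function() {
    gap <- cluster::clusGap(Xv, FUN = function(x, k) {
      stats::kmeans(x, k, nstart = 5, iter.max = 30)
    }, K.max = k_max, B = B, spaceH0 = "original", verbose = FALSE)
    unname(which.max(gap$Tab[, "gap"]))
  })
  list(ch = ch, silhouette = sil, gap_k = gap_k)
}
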