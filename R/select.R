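# Hybrid feature selection: ReliefF instance-based weights, Pearson
# correlation with the target, min-max rescaling of both signals, a convex
# combination, and ranking.

#' ReliefF feature weights
#'
#' Multi-class ReliefF with k nearest hits and, per other class, k nearest
#' misses weighted by class prior. Features are min-max scaled internally
#' and distances are L1 on the scaled features. For each evaluated instance,
#' every feature's weight is updated by `delta * (NMAD_f - NHD_f)` where
#' `NHD_f` is the mean per-feature distance to the nearest hits and `NMAD_f`
#' the prior-weighted mean over other classes of the per-feature distance to
#' that class's nearest misses (the classical orientation: hits near and
#' misses far give a high weight). `delta = 1/m` with `m` evaluated
#' instances, so weights are averages in `[-1, 1]`. `literal_sign = TRUE`
#' flips the update to `delta * (NHD_f - NMAD_f)`.
#'
#' Neighbor ties are broken by ascending sample index (stable sort), and the
#' evaluation order is the deterministic sample order unless `n_iterations`
#' is smaller than `n`, in which case instances are subsampled with `seed`.
#'
#' @param X a [feature_table] with at least 2 classes.
#' @param k_neighbors neighbors per class (must be < smallest class size).
#' @param n_iterations instances to evaluate (default: all, in order).
#' @param seed RNG seed for subsampling.
#' @param literal_sign use the `(NHD - NMAD)` update orientation.
#' @return Named numeric vector of per-feature weights.
#' @export
relieff_weights <- function(X, k_neighbors = 10L, n_iterations = NULL,
                            seed = 1L, literal_sign = FALSE) {
  stopifnot(inherits(X, "feature_table"))
  k <- check_count(k_neighbors, "k_neighbors")
  y <- X$labels
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop_invalid("ReliefF requires at least 2 classes")
  counts <- table(factor(y, levels = classes))
  if (k >= min(counts))
    stop_invalid("k_neighbors (", k, ") must be smaller than the smallest ",
                 "class size (", min(counts), ")")
  S <- apply(X$values, 2, rescale01)
  n <- nrow(S); p <- ncol(S)
  priors <- as.numeric(counts) / n
  names(priors) <- classes
  m <- if (is.null(n_iterations)) n else check_count(n_iterations, "n_iterations")
  idx <- if (m >= n) seq_len(n) else with_seed(seed, sample.int(n, m))
  m <- length(idx)
  w <- numeric(p)
  class_rows <- lapply(classes, function(cl) which(y == cl))
  for (i in idx) {
    diffs <- abs(S - matrix(S[i, ], n, p, byrow = TRUE))
    d <- rowSums(diffs)
    yi <- as.character(y[i])
    upd <- numeric(p)
    for (ci in seq_along(classes)) {
      rows <- class_rows[[ci]]
      if (classes[ci] == y[i]) rows <- setdiff(rows, i)
      nb <- rows[order(d[rows], rows)][seq_len(k)]
      mean_diff <- colMeans(diffs[nb, , drop = FALSE])
      if (classes[ci] == y[i]) upd <- upd - mean_diff
      else upd <- upd + priors[ci] / (1 - priors[yi]) * mean_diff
    }
    if (literal_sign) upd <- -upd
    w <- w + upd / m
  }
  stats::setNames(w, X$names)
}

#' Pearson correlation of each feature with the target
#'
#' `tau = cov(a_i, b) / (sigma_a sigma_b)` against the integer-coded label.
#' A constant feature (or constant target) has undefined correlation and is
#' assigned 0 with a warning.
#'
#' @param X a [feature_table].
#' @return Named numeric vector of correlations in `[-1, 1]`.
#' @export
pearson_scores <- function(X) {
  stopifnot(inherits(X, "feature_table"))
  y <- as.numeric(X$labels)
  tau <- vapply(seq_len(ncol(X$values)), function(j) {
    v <- X$values[, j]
    if (stats::sd(v) == 0 || stats::sd(y) == 0) {
      warning("constant feature or target; correlation defined as 0 for '",
              X$names[j], "'")
      return(0)
    }
    stats::cor(v, y)
  }, numeric(1))
  stats::setNames(tau, X$names)
}

#' Combine ReliefF and Pearson signals into a hybrid score
#'
#' Takes `|pearson|`, min-max rescales both signals to `[0, 1]`, and forms
#' the convex combination `alpha * relieff_scaled +
#' (1 - alpha) * pearson_scaled`. Ranks are 1-based by decreasing combined
#' score with ties broken by ascending feature index.
#'
#' @param relieff per-feature ReliefF weights.
#' @param pearson per-feature correlations.
#' @param alpha mixing weight in `[0, 1]` (1 = ReliefF only).
#' @return A `selection_scores` data frame with columns `feature`,
#'   `relieff`, `pearson`, `relieff_scaled`, `pearson_scaled`, `combined`,
#'   `rank`.
#' @export
combine_scores <- function(relieff, pearson, alpha = 0.5) {
  if (length(relieff) != length(pearson))
    stop_invalid("relieff and pearson lengths differ")
  alpha <- check_fraction(alpha, "alpha")
  rf_s <- rescale01(relieff)
  pc_s <- rescale01(abs(pearson))
  comb <- alpha * rf_s + (1 - alpha) * pc_s
  ord <- order(-comb, seq_along(comb))
  rank <- integer(length(comb)); rank[ord] <- seq_along(comb)
  nm <- if (!is.null(names(relieff))) names(relieff)
        else paste0("f", seq_along(relieff))
  structure(data.frame(feature = nm, relieff = as.numeric(relieff),
                       pearson = as.numeric(pearson),
                       relieff_scaled = rf_s, pearson_scaled = pc_s,
                       combined = comb, rank = rank,
                       stringsAsFactors = FALSE),
            class = c("selection_scores", "data.frame"))
}

#' Select top features by hybrid score
#'
#' Either the `k` best-ranked features or all features whose combined score
#' meets `threshold`. A threshold above the maximum yields an empty set with
#' a warning.
#'
#' @param scores a [combine_scores()] result.
#' @param k number of features to keep.
#' @param threshold minimal combined score (used when `k` is NULL).
#' @return Integer vector of selected feature indices (rank order).
#' @export
select_top <- function(scores, k = NULL, threshold = NULL) {
  stopifnot(inherits(scores, "selection_scores"))
  if (is.null(k) && is.null(threshold))
    stop_invalid("provide k or threshold")
  if (!is.null(k)) {
    k <- check_count(k, "k")
    k <- min(k, nrow(scores))
    return(order(scores$rank)[seq_len(k)])
  }
  sel <- which(scores$combined >= threshold)
  if (!length(sel)) {
    warning("threshold ", threshold, " exceeds the maximal combined score; ",
            "empty selection")
    return(integer(0))
  }
  sel[order(scores$rank[sel])]
}

#' Run the full hybrid selection on a feature table
#'
#' Convenience wrapper: ReliefF weights, Pearson scores, combination and
#' ranking in one call.
#'
#' @inheritParams relieff_weights
#' @inheritParams combine_scores
#' @return A `selection_scores` data frame.
#' @export
hybrid_selection <- function(X, k_neighbors = 10L, n_iterations = NULL,
                             alpha = 0.5, seed = 1L) {
  rf <- relieff_weights(X, k_neighbors, n_iterations, seed)
  pc <- suppressWarnings(pearson_scores(X))
  combine_scores(rf, pc, alpha)
}
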