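#' First-order Accumulated Local Effects curve
#'
#' Model-agnostic main-effect curve of one feature: the feature range is
#' cut into (up to) `n_bins` equal-count quantile bins; within each bin
#' the prediction difference obtained by moving every observation in the
#' bin from the bin's lower to its upper edge is averaged; the bin
#' effects are accumulated by a cumulative sum and centered so the
#' count-weighted mean effect over the data (interpolated at bin
#' midpoints) is zero. Because only *local* finite differences are
#' averaged, the curve remains faithful when features are correlated —
#' the property that motivates ALE over partial dependence.
#'
#' @param predict_fn Function `data.frame -> numeric` returning model
#'   predictions (e.g. `function(d) predict(forest, d)`).
#' @param data data.frame of observations (the feature distribution used
#'   for binning).
#' @param feature Column name.
#' @param n_bins Target number of quantile bins (default 20; duplicate
#'   quantile edges are collapsed, so fewer bins may result).
#' @return An object of class `ale_curve`: list with `feature`, `edges`
#'   (length K+1), `effect` (length K+1, years, centered), `counts`
#'   (length K).
#' @export
ale_first_order <- function(predict_fn, data, feature, n_bins = 20) {
  x <- data[[feature]]
  if (is.null(x)) stop("unknown feature: ", feature)
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  K <- length(edges) - 1
  if (K < 1) stop("constant feature: ", feature, " (no effect estimable)")
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  d_hi <- data; d_hi[[feature]] <- edges[bin + 1]
  d_lo <- data; d_lo[[feature]] <- edges[bin]
  diffs <- predict_fn(d_hi) - predict_fn(d_lo)
  counts <- tabulate(bin, nbins = K)
  delta <- vapply(seq_len(K), function(k) {
    if (counts[k] == 0) 0 else mean(diffs[bin == k])
  }, numeric(1))
  fj <- c(0, cumsum(delta))
  center <- sum(counts * (fj[seq_len(K)] + fj[seq_len(K) + 1]) / 2) /
    sum(counts)
  structure(list(feature = feature, edges = edges, effect = fj - center,
                 counts = counts),
            class = "ale_curve")
}

# fill empty cells of a K1 x K2 matrix with the value of the nearest
# non-empty cell (bin-index Euclidean distance; ties averaged)
fill_empty_cells <- function(m) {
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx) == 0) return(m)
  ok_idx <- which(!is.na(m), arr.ind = TRUE)
  if (nrow(ok_idx) == 0) stop("all cells empty")
  out <- m
  for (i in seq_len(nrow(na_idx))) {
    d2 <- (ok_idx[, 1] - na_idx[i, 1])^2 + (ok_idx[, 2] - na_idx[i, 2])^2
    near <- which(d2 == min(d2))
    out[na_idx[i, 1], na_idx[i, 2]] <-
      mean(m[ok_idx[near, , drop = FALSE]])
  }
  out
}

#' Second-order Accumulated Local Effects surface
#'
#' Pure two-feature interaction effect: per 2D quantile-bin cell, the
#' mean second difference of predictions over the cell's corners is
#' accumulated in both directions, the first-order (main) effects
#' implied by the accumulated surface are subtracted, and the result is
#' doubly centered so count-weighted row and column means are zero. The
#' surface of an additive model is identically zero.
#'
#' @param predict_fn Function `data.frame -> numeric`.
#' @param data data.frame of observations.
#' @param features Character vector of two column names.
#' @param n_bins Target bins per feature (default 10).
#' @return Object of class `ale_surface`: list with `features`,
#'   `edges1`, `edges2` (lengths K1+1, K2+1), `effect` ((K1+1) x (K2+1)
#'   matrix, years), `counts` (K1 x K2).
#' @export
ale_second_order <- function(predict_fn, data, features, n_bins = 10) {
  stopifnot(length(features) == 2)
  x1 <- data[[features[1]]]; x2 <- data[[features[2]]]
  if (is.null(x1) || is.null(x2)) stop("unknown feature(s)")
  e1 <- unique(stats::quantile(x1, seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  e2 <- unique(stats::quantile(x2, seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  K1 <- length(e1) - 1; K2 <- length(e2) - 1
  if (K1 < 1) stop("constant feature: ", features[1])
  if (K2 < 1) stop("constant feature: ", features[2])
  b1 <- findInterval(x1, e1, rightmost.closed = TRUE, all.inside = TRUE)
  b2 <- findInterval(x2, e2, rightmost.closed = TRUE, all.inside = TRUE)
  n <- nrow(data)

  pred_at <- function(v1, v2) {
    d <- data; d[[features[1]]] <- v1; d[[features[2]]] <- v2
    predict_fn(d)
  }
  second_diff <- pred_at(e1[b1 + 1], e2[b2 + 1]) -
    pred_at(e1[b1], e2[b2 + 1]) -
    pred_at(e1[b1 + 1], e2[b2]) +
    pred_at(e1[b1], e2[b2])

  counts <- matrix(0L, K1, K2)
  delta <- matrix(NA_real_, K1, K2)
  cell <- (b2 - 1L) * K1 + b1
  agg_n <- tabulate(cell, nbins = K1 * K2)
  agg_s <- vapply(seq_len(K1 * K2), function(cc) {
    sum(second_diff[cell == cc])
  }, numeric(1))
  counts[] <- agg_n
  delta[] <- ifelse(agg_n > 0, agg_s / pmax(agg_n, 1L), NA_real_)
  delta <- fill_empty_cells(delta)

  fj <- apply(delta, 2, cumsum)
  fj <- t(apply(fj, 1, cumsum))
  fj <- rbind(0, fj); fj <- cbind(0, fj)  # (K1+1) x (K2+1), zero edges

  # subtract the first-order components implied by the surface
  rs <- rowSums(counts); cs <- colSums(counts)
  D1 <- fj[2:(K1 + 1), , drop = FALSE] - fj[1:K1, , drop = FALSE]
  D1_ave <- (D1[, 1:K2, drop = FALSE] + D1[, 2:(K2 + 1), drop = FALSE]) / 2
  f1 <- c(0, cumsum(rowSums(counts * D1_ave) / pmax(rs, 1L)))
  D2 <- fj[, 2:(K2 + 1), drop = FALSE] - fj[, 1:K2, drop = FALSE]
  D2_ave <- (D2[1:K1, , drop = FALSE] + D2[2:(K1 + 1), , drop = FALSE]) / 2
  f2 <- c(0, cumsum(colSums(counts * D2_ave) / pmax(cs, 1L)))
  fj <- fj - outer(f1, rep(1, K2 + 1)) - outer(rep(1, K1 + 1), f2)

  f0 <- sum(counts * (fj[1:K1, 1:K2] + fj[2:(K1 + 1), 1:K2] +
                        fj[1:K1, 2:(K2 + 1)] +
                        fj[2:(K1 + 1), 2:(K2 + 1)]) / 4) / n
  fj <- fj - f0
  structure(list(features = features, edges1 = e1, edges2 = e2,
                 effect = fj, counts = counts),
            class = "ale_surface")
}
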