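# out-of-bag forest predictions: each observation is predicted only by
# the trees in which it was out of bag
oob_predictions <- function(forest, x) {
  inbag <- forest$inbag
  if (is.null(inbag)) {
    stop("forest lacks in-bag structure; fit with keep.inbag = TRUE ",
         "(fit_age_model does this)")
  }
  per_tree <- stats::predict(forest, x, predict.all = TRUE)$individual
  oob <- inbag == 0
  n_oob <- rowSums(oob)
  if (any(n_oob == 0)) {
    stop("some training observations are in-bag in every tree; ",
         "increase the number of trees")
  }
  rowSums(per_tree * oob) / n_oob
}

# OOB MSE of the bundle's forest on its training data with one feature
# column replaced by a permuted copy (perm = identity gives the baseline)
oob_mse_permuted <- function(bundle, feature, perm) {
  x <- bundle$train_x
  x[[feature]] <- x[[feature]][perm]
  mean((oob_predictions(bundle$forest, x) - bundle$train_y)^2)
}

#' Out-of-bag permutation feature importance
#'
#' For each feature, the increase in out-of-bag mean squared error when
#' that feature's column is randomly permuted across the training
#' observations, averaged over `n_permutations` seeded permutations.
#' Every observation is evaluated only on trees where it was out of bag.
#' Larger `delta_mse` (in squared years) means the model leans more on
#' the feature; no directionality is implied.
#'
#' @param bundle An `age_model_bundle` from [fit_age_model()].
#' @param seed Integer seed for the permutations.
#' @param n_permutations Permutation repeats averaged per feature
#'   (default 5).
#' @return data.frame of class `importance_table`: `feature`,
#'   `delta_mse` (years squared), `rank` (1 = most important), sorted by
#'   rank. Attribute `baseline_oob_mse` carries the unpermuted OOB MSE.
#' @export
permutation_importance <- function(bundle, seed = 1L, n_permutations = 5L) {
  stopifnot(inherits(bundle, "age_model_bundle"))
  n <- nrow(bundle$train_x)
  baseline <- mean((oob_predictions(bundle$forest, bundle$train_x) -
                      bundle$train_y)^2)
  feats <- bundle$feature_names
  set.seed(seed)
  perms <- replicate(n_permutations, sample.int(n), simplify = FALSE)
  delta <- vapply(feats, function(f) {
    mean(vapply(perms, function(p) oob_mse_permuted(bundle, f, p),
                numeric(1))) - baseline
  }, numeric(1))
  out <- data.frame(feature = feats, delta_mse = unname(delta),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$delta_mse, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "baseline_oob_mse") <- baseline
  class(out) <- c("importance_table", "data.frame")
  out
}
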