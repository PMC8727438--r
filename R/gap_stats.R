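#' Root mean squared error
#'
#' @param pred,actual Equal-length numeric vectors.
#' @return `sqrt(mean((pred - actual)^2))`, in years.
#' @export
rmse <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("length mismatch")
  if (length(pred) == 0) stop("empty input")
  sqrt(mean((pred - actual)^2))
}

#' Breiman's pseudo R-squared
#'
#' `1 - MSE(pred, actual) / Var(actual)`, with the population (n
#' denominator) variance, the forest-community analogue of R-squared.
#' Zero for the constant mean predictor, one for perfect prediction,
#' negative for predictors worse than the mean.
#'
#' @param pred,actual Equal-length numeric vectors; `actual` must have
#'   nonzero variance.
#' @return A single double, at most 1.
#' @export
pseudo_r_squared <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("length mismatch")
  v <- mean((actual - mean(actual))^2)
  if (v == 0) stop("zero-variance actual values")
  1 - mean((pred - actual)^2) / v
}

#' Median absolute error
#'
#' @param pred,actual Equal-length numeric vectors.
#' @return `median(|pred - actual|)`, in years.
#' @export
median_absolute_error <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("length mismatch")
  if (length(pred) == 0) stop("empty input")
  stats::median(abs(pred - actual))
}

#' Evaluate a set of prediction records
#'
#' @param predictions data.frame from [predict_age()].
#' @return One-row data.frame: `model_id` (if present in attributes),
#'   `partition`, `n`, `rmse`, `pseudo_r2`, `median_abs_error`.
#' @export
evaluate_predictions <- function(predictions) {
  data.frame(
    partition = predictions$partition[1],
    n = nrow(predictions),
    rmse = rmse(predictions$age_pred, predictions$age_true),
    pseudo_r2 = pseudo_r_squared(predictions$age_pred, predictions$age_true),
    median_abs_error = median_absolute_error(predictions$age_pred,
                                             predictions$age_true))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Input p-values sorted ascending are multiplied by `(k - rank + 1)`,
#' made monotone by a cumulative maximum, capped at 1, and returned in
#' the original order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order; always `>=` the raw values.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Paired comparison of two models' absolute errors
#'
#' Two-sided Wilcoxon signed-rank test on the per-subject differences of
#' absolute prediction errors (statistic V). Uses the conventional exact
#' null for small samples without ties/zeros and the normal approximation
#' with continuity correction otherwise.
#'
#' @param abs_errors_m1,abs_errors_m2 Absolute errors for the same
#'   subjects, in the same order.
#' @return data.frame: `statistic_name` (`"signed_rank_V"`), `statistic`,
#'   `p_raw`, `median_m1`, `median_m2`, `comparison_id`.
#' @export
compare_models_paired <- function(abs_errors_m1, abs_errors_m2) {
  if (length(abs_errors_m1) != length(abs_errors_m2)) stop("length mismatch")
  d <- abs_errors_m1 - abs_errors_m2
  if (all(d == 0)) stop("degenerate paired test: all differences are zero")
  ht <- suppressWarnings(stats::wilcox.test(abs_errors_m1, abs_errors_m2,
                                            paired = TRUE))
  data.frame(statistic_name = "signed_rank_V",
             statistic = unname(ht$statistic),
             p_raw = ht$p.value,
             median_m1 = stats::median(abs_errors_m1),
             median_m2 = stats::median(abs_errors_m2),
             comparison_id = "model1_vs_model2_abs_error",
             stringsAsFactors = FALSE)
}

#' Brain-age-gap comparisons by screen status
#'
#' Two two-sided Wilcoxon rank-sum tests on the validation prediction
#' records: raw errors (the brain-age gap, predicted minus actual) and
#' absolute errors, positive-screen group versus negative-screen group.
#' The two p-values form one Holm-Bonferroni family.
#'
#' @param predictions data.frame from [predict_age()] with non-missing
#'   `mdq_positive`.
#' @return data.frame with one row per comparison (`raw_error`,
#'   `abs_error`): statistic W (rank-sum of the positive group over the
#'   negative group), `p_raw`, `p_adjusted`, and the two group medians.
#' @export
compare_groups_by_mdq <- function(predictions) {
  pos <- predictions[predictions$mdq_positive %in% TRUE, , drop = FALSE]
  neg <- predictions[predictions$mdq_positive %in% FALSE, , drop = FALSE]
  if (nrow(pos) == 0) stop("empty group: mdq_positive")
  if (nrow(neg) == 0) stop("empty group: mdq_negative")
  one <- function(col) {
    ht <- suppressWarnings(stats::wilcox.test(pos[[col]], neg[[col]]))
    data.frame(comparison_id = col,
               statistic_name = "rank_sum_W",
               statistic = unname(ht$statistic),
               p_raw = ht$p.value,
               median_positive = stats::median(pos[[col]]),
               median_negative = stats::median(neg[[col]]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("raw_error"), one("abs_error"))
  out$p_adjusted <- holm_bonferroni(out$p_raw)
  out
}
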