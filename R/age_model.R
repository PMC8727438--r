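#' Tuning configuration for the random-forest age models
#'
#' @param mtry_grid Candidate numbers of split variables (default 1:30).
#' @param cv_folds Cross-validation folds (default 10).
#' @param cv_repeats Repeats of the CV (default 3).
#' @param n_trees Trees per forest (default 500, the default of the
#'   forest implementation used).
#' @param split_fraction Training fraction of the subject-level split
#'   (default 0.75).
#' @param seed Integer seed controlling the split, fold assignment and
#'   forest fitting.
#' @return List of class `tune_config`.
#' @export
tune_config <- function(mtry_grid = 1:30, cv_folds = 10L, cv_repeats = 3L,
                        n_trees = 500L, split_fraction = 0.75, seed = 1L) {
  stopifnot(length(mtry_grid) >= 1, all(mtry_grid >= 1), cv_folds >= 2,
            cv_repeats >= 1, n_trees >= 1,
            split_fraction > 0, split_fraction < 1)
  structure(list(mtry_grid = sort(unique(as.integer(mtry_grid))),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 n_trees = as.integer(n_trees),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "tune_config")
}

#' Model identifiers
#'
#' Model 1 uses only the 30 typing features; Model 2 adds the gender
#' indicator and the screen status.
#' @export
MODEL_IDS <- c("model1_typing_only", "model2_plus_gender_mdq")

#' Predictor columns of a model
#'
#' @param model_id One of [MODEL_IDS].
#' @return Character vector of predictor column names (30 for Model 1,
#'   32 for Model 2).
#' @export
model_predictors <- function(model_id = MODEL_IDS) {
  model_id <- match.arg(model_id)
  if (model_id == "model1_typing_only") typing_feature_names()
  else c(typing_feature_names(), "gender_not_male", "mdq_positive")
}

#' Split subjects into training and validation sets
#'
#' Simple random (unstratified) split: `ceiling(split_fraction * n)`
#' subjects train, the rest validate.
#'
#' @param subject_ids Character vector of ids.
#' @param split_fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with `train` and `validation` id vectors.
#' @export
split_train_validation <- function(subject_ids, split_fraction = 0.75,
                                   seed = 1L) {
  n <- length(subject_ids)
  if (n < 8) stop("too few subjects to split (need >= 8, got ", n, ")")
  n_train <- ceiling(split_fraction * n)
  set.seed(seed)
  train <- sort(sample(subject_ids, n_train))
  list(train = train, validation = sort(setdiff(subject_ids, train)))
}

# median imputation: learn per-column medians on training data
impute_medians <- function(x) {
  meds <- vapply(x, function(col) stats::median(col, na.rm = TRUE),
                 numeric(1))
  bad <- names(meds)[!is.finite(meds)]
  if (length(bad) > 0) {
    stop("feature(s) entirely missing in training data: ",
         paste(bad, collapse = ", "))
  }
  meds
}

apply_imputation <- function(x, medians) {
  for (cl in names(medians)) {
    v <- x[[cl]]
    v[is.na(v)] <- medians[[cl]]
    x[[cl]] <- v
  }
  x
}

#' Tune mtry by repeated k-fold cross-validation
#'
#' Grid search over `config$mtry_grid`: for each candidate, fold RMSEs
#' over `cv_folds x cv_repeats` seeded fold assignments are averaged; the
#' candidate minimizing mean CV RMSE is chosen, ties broken toward the
#' smallest value. Candidates exceeding the predictor count are skipped
#' with a warning. Within each fold, missing features are imputed with
#' the fold-training medians.
#'
#' @param x data.frame of predictors (missing values allowed).
#' @param y Numeric ages.
#' @param config A [tune_config()] object.
#' @return List with `chosen_mtry` and `tuning_trace` (data.frame
#'   `mtry`, `cv_rmse`).
#' @export
tune_mtry <- function(x, y, config = tune_config()) {
  stopifnot(nrow(x) == length(y), !anyNA(y))
  p <- ncol(x)
  grid <- config$mtry_grid
  if (any(grid > p)) {
    warning("skipping mtry value(s) exceeding predictor count (",
            p, "): ", paste(grid[grid > p], collapse = ", "))
    grid <- grid[grid <= p]
  }
  if (length(grid) == 0) stop("empty mtry grid after filtering")
  n <- nrow(x)
  rmse_sum <- stats::setNames(numeric(length(grid)), grid)
  n_eval <- 0L
  for (rep_i in seq_len(config$cv_repeats)) {
    set.seed(config$seed + 1000L * rep_i)
    folds <- sample(rep(seq_len(config$cv_folds), length.out = n))
    for (fold_i in seq_len(config$cv_folds)) {
      holdout <- folds == fold_i
      meds <- impute_medians(x[!holdout, , drop = FALSE])
      xtr <- apply_imputation(x[!holdout, , drop = FALSE], meds)
      xte <- apply_imputation(x[holdout, , drop = FALSE], meds)
      for (g in seq_along(grid)) {
        set.seed(config$seed + 7919L * rep_i + 131L * fold_i + g)
        fit <- randomForest::randomForest(
          x = xtr, y = y[!holdout], ntree = config$n_trees, mtry = grid[g])
        pred <- stats::predict(fit, xte)
        rmse_sum[g] <- rmse_sum[g] + rmse(pred, y[holdout])
      }
    }
  }
  trace <- data.frame(mtry = grid,
                      cv_rmse = rmse_sum / (config$cv_folds * config$cv_repeats))
  chosen <- trace$mtry[which.min(trace$cv_rmse)]  # grid sorted: tie -> smallest
  list(chosen_mtry = chosen, tuning_trace = trace)
}

#' Fit a random-forest age model
#'
#' Missing predictor values are imputed with training medians (stored in
#' the bundle and reused verbatim at prediction time, so no information
#' leaks from validation data). The forest keeps its in-bag structure so
#' out-of-bag errors and permutation importance can be computed later.
#'
#' @param x data.frame of training predictors.
#' @param y Numeric training ages (no missing values).
#' @param model_id One of [MODEL_IDS].
#' @param chosen_mtry Number of split candidates per node.
#' @param config A [tune_config()] object (supplies `n_trees` and the
#'   fitting seed).
#' @param tuning_trace Optional tuning trace to store in the bundle.
#' @param subject_ids Optional training subject ids.
#' @return An `age_model_bundle`: list with the fitted `forest`,
#'   `model_id`, `chosen_mtry`, `tuning_trace`, `feature_names`,
#'   `imputation_values`, `training_subject_ids`, `train_x` (imputed),
#'   `train_y`.
#' @export
fit_age_model <- function(x, y, model_id = MODEL_IDS, chosen_mtry,
                          config = tune_config(), tuning_trace = NULL,
                          subject_ids = NULL) {
  model_id <- match.arg(model_id)
  stopifnot(nrow(x) == length(y), !anyNA(y))
  wanted <- model_predictors(model_id)
  missing_cols <- setdiff(wanted, names(x))
  if (length(missing_cols) > 0) {
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[, wanted, drop = FALSE]
  x[] <- lapply(x, as.numeric)
  meds <- impute_medians(x)
  xi <- apply_imputation(x, meds)
  set.seed(config$seed + 7L)
  forest <- randomForest::randomForest(
    x = xi, y = y, ntree = config$n_trees,
    mtry = min(chosen_mtry, ncol(xi)),
    keep.forest = TRUE, keep.inbag = TRUE)
  structure(list(model_id = model_id, forest = forest,
                 chosen_mtry = as.integer(chosen_mtry),
                 tuning_trace = tuning_trace,
                 feature_names = wanted, imputation_values = meds,
                 training_subject_ids = subject_ids,
                 train_x = xi, train_y = y),
            class = "age_model_bundle")
}

#' Tune and fit one of the two stepwise models from a feature table
#'
#' Convenience wrapper: selects the model's predictors from a feature
#' table, tunes `mtry` with [tune_mtry()] and fits the final forest on
#' the full training table.
#'
#' @param feature_table data.frame with `subject_id`, the typing
#'   features, `gender_not_male`, `mdq_positive`, `age`.
#' @param model_id One of [MODEL_IDS].
#' @param config A [tune_config()] object.
#' @return An `age_model_bundle`.
#' @export
train_age_model <- function(feature_table, model_id = MODEL_IDS,
                            config = tune_config()) {
  model_id <- match.arg(model_id)
  wanted <- model_predictors(model_id)
  x <- as.data.frame(feature_table)[, wanted, drop = FALSE]
  x[] <- lapply(x, as.numeric)
  y <- feature_table$age
  tuned <- tune_mtry(x, y, config)
  fit_age_model(x, y, model_id, tuned$chosen_mtry, config,
                tuning_trace = tuned$tuning_trace,
                subject_ids = feature_table$subject_id)
}

#' Predict ages and brain-age gaps for new subjects
#'
#' Missing features are imputed with the bundle's stored training
#' medians. The raw prediction error (`age_pred - age_true`) is the
#' brain-age gap: negative values mean the subject types "younger" than
#' their chronological age.
#'
#' @param bundle An `age_model_bundle`.
#' @param feature_table data.frame with `subject_id`, the bundle's
#'   feature columns, `age`, and `mdq_positive`.
#' @param partition Label stored in the output (`"validation"` by
#'   default).
#' @return data.frame of prediction records: `subject_id`, `age_true`,
#'   `age_pred`, `raw_error`, `abs_error`, `mdq_positive`, `partition`.
#' @export
predict_age <- function(bundle, feature_table, partition = "validation") {
  stopifnot(inherits(bundle, "age_model_bundle"))
  missing_cols <- setdiff(bundle$feature_names, names(feature_table))
  if (length(missing_cols) > 0) {
    stop("feature table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(feature_table)[, bundle$feature_names, drop = FALSE]
  x[] <- lapply(x, as.numeric)
  x <- apply_imputation(x, bundle$imputation_values)
  pred <- stats::predict(bundle$forest, x)
  out <- data.frame(
    subject_id = feature_table$subject_id,
    age_true = as.numeric(feature_table$age),
    age_pred = as.numeric(pred),
    stringsAsFactors = FALSE)
  out$raw_error <- out$age_pred - out$age_true
  out$abs_error <- abs(out$raw_error)
  out$mdq_positive <- if ("mdq_positive" %in% names(feature_table))
    as.logical(feature_table$mdq_positive) else NA
  out$partition <- partition
  rownames(out) <- NULL
  out
}
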