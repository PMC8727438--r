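#' Default pipeline configuration
#'
#' One configuration object drives the whole analysis. A single
#' `master_seed` deterministically derives per-stage seeds (stage k uses
#' `(master_seed + 1000003 * k) mod (2^31 - 1)`), so individual stages
#' can be re-run independently and the full run is bit-reproducible.
#'
#' @param cohort A [cohort_params()] object (used when simulating).
#' @param tune A [tune_config()] object.
#' @param entropy A [sampen_params()] object.
#' @param gap_threshold Session gap in seconds (default 5).
#' @param min_weeks Inclusion threshold (default 12; `NULL` disables).
#' @param alpha Two-sided significance level (default 0.05).
#' @param n_ale_features Number of top-importance features to plot ALE
#'   curves for (default 4, as in the headline analysis).
#' @param importance_permutations Permutation repeats for importance.
#' @param master_seed Integer master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_params(), tune = tune_config(),
                       entropy = sampen_params(), gap_threshold = 5,
                       min_weeks = 12, alpha = 0.05, n_ale_features = 4,
                       importance_permutations = 5L, master_seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(cohort = cohort, tune = tune, entropy = entropy,
                 gap_threshold = gap_threshold, min_weeks = min_weeks,
                 alpha = alpha, n_ale_features = n_ale_features,
                 importance_permutations = as.integer(importance_permutations),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Derive a per-stage seed from the master seed
#'
#' @param master_seed Integer master seed.
#' @param stage Integer stage index.
#' @return Integer seed below 2^31 - 1.
#' @export
stage_seed <- function(master_seed, stage) {
  as.integer((as.double(master_seed) + 1000003 * stage) %% 2147483647)
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys: `cohort`, `tune`, `entropy` (each a map of
#' the corresponding constructor's arguments), plus `gap_threshold`,
#' `min_weeks`, `alpha`, `n_ale_features`, `importance_permutations`,
#' `master_seed`. Missing keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cp <- do.call(cohort_params, y$cohort %||% list())
  tc <- do.call(tune_config, y$tune %||% list())
  ep <- do.call(sampen_params, y$entropy %||% list())
  run_config(cohort = cp, tune = tc, entropy = ep,
             gap_threshold = y$gap_threshold %||% 5,
             min_weeks = y$min_weeks %||% 12,
             alpha = y$alpha %||% 0.05,
             n_ale_features = y$n_ale_features %||% 4,
             importance_permutations = y$importance_permutations %||% 5L,
             master_seed = y$master_seed %||% 1L)
}

#' Run the full analysis pipeline
#'
#' simulate (or ingest) -> featurize -> split -> tune and fit the two
#' stepwise models -> evaluate -> compare groups -> interpret. Writes
#' `features.csv`, per-model `tuning_trace_*.csv` and `predictions.csv`,
#' `evaluation.json` (validation RMSE, pseudo R-squared, median absolute
#' error per model plus the paired model comparison),
#' `group_comparison.json` (raw/absolute error rank-sum comparisons with
#' Holm adjustment), figures, and `manifest.json` with seeds and input
#' provenance. All outputs are pure functions of (inputs, config,
#' master_seed).
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory.
#' @param events Optional event table; when `NULL` a cohort is simulated
#'   from `config$cohort`.
#' @param metadata Optional metadata table (required with `events`).
#' @param render_figures Write PDF figures (default TRUE).
#' @return Invisibly, a list with `features`, `bundles`, `predictions`,
#'   `evaluation`, `model_comparison`, `group_comparison`, `importance`,
#'   `ale_curves`, `ale_surfaces`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         events = NULL, metadata = NULL,
                         render_figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ms <- config$master_seed
  simulated <- is.null(events)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (simulated) {
    cohort <- stage("simulate", {
      cp <- config$cohort
      cp$seed <- stage_seed(ms, 1L)
      generate_cohort(cp)
    })
    events <- cohort$events
    metadata <- cohort$metadata
    write_event_log(events, file.path(out_dir, "events.csv"))
    data.table::fwrite(metadata, file.path(out_dir, "metadata.csv"))
    data.table::fwrite(cohort$profiles, file.path(out_dir, "truth.csv"))
  } else if (is.null(metadata)) {
    stop("metadata must be supplied with events")
  }

  features <- stage("featurize", compute_features(
    events, metadata, gap_threshold = config$gap_threshold,
    entropy = config$entropy, min_weeks = config$min_weeks))
  write_feature_table(features, file.path(out_dir, "features.csv"))

  split <- stage("split", split_train_validation(
    features$subject_id, config$tune$split_fraction, stage_seed(ms, 2L)))
  train_tab <- features[features$subject_id %in% split$train, ]
  valid_tab <- features[features$subject_id %in% split$validation, ]

  bundles <- list(); predictions <- list(); evaluation <- list()
  for (k in seq_along(MODEL_IDS)) {
    mid <- MODEL_IDS[k]
    tc <- config$tune
    tc$seed <- stage_seed(ms, 10L + k)
    bundle <- stage(paste0("train_", mid),
                    train_age_model(train_tab, mid, tc))
    pred_v <- predict_age(bundle, valid_tab, partition = "validation")
    pred_t <- predict_age(bundle, train_tab, partition = "train")
    ev <- cbind(model_id = mid, rbind(evaluate_predictions(pred_v),
                                      evaluate_predictions(pred_t)))
    ev$chosen_mtry <- bundle$chosen_mtry
    bundles[[mid]] <- bundle
    predictions[[mid]] <- rbind(pred_v, pred_t)
    evaluation[[mid]] <- ev
    data.table::fwrite(bundle$tuning_trace,
                       file.path(out_dir, paste0("tuning_trace_", mid, ".csv")))
  }
  evaluation <- do.call(rbind, evaluation)
  pred_all <- data.table::rbindlist(predictions, idcol = "model_id")
  data.table::fwrite(pred_all, file.path(out_dir, "predictions.csv"))

  v1 <- predictions[[1]][predictions[[1]]$partition == "validation", ]
  v2 <- predictions[[2]][predictions[[2]]$partition == "validation", ]
  model_cmp <- stage("compare_models", {
    stopifnot(identical(v1$subject_id, v2$subject_id))
    compare_models_paired(v1$abs_error, v2$abs_error)
  })
  group_cmp <- stage("compare_groups", compare_groups_by_mdq(v2))

  jsonlite::write_json(
    list(models = evaluation, model_comparison = model_cmp,
         alpha = config$alpha),
    file.path(out_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  jsonlite::write_json(
    group_cmp, file.path(out_dir, "group_comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")

  # interpretation on the headline model (Model 2)
  b2 <- bundles[[2]]
  imp <- stage("importance", permutation_importance(
    b2, seed = stage_seed(ms, 20L),
    n_permutations = config$importance_permutations))
  pfun <- function(d) as.numeric(stats::predict(
    b2$forest, apply_imputation(d[, b2$feature_names, drop = FALSE],
                                b2$imputation_values)))
  top <- utils::head(imp$feature, config$n_ale_features)
  full_tab <- rbind(train_tab, valid_tab)
  curves <- stage("ale", lapply(top, function(f) {
    ale_first_order(pfun, full_tab, f)
  }))
  surfaces <- stage("ale2", if (length(top) >= 2) {
    list(ale_second_order(pfun, full_tab, top[1:2]))
  } else list())

  if (render_figures) {
    render_reports(file.path(out_dir, "figures"), importance = imp,
                   curves = curves, surfaces = surfaces,
                   evaluation = evaluation, group_comparison = group_cmp,
                   predictions = v2,
                   tuning_traces = lapply(bundles, `[[`, "tuning_trace"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("typeage")),
    master_seed = ms,
    stage_seeds = list(simulate = stage_seed(ms, 1L),
                       split = stage_seed(ms, 2L),
                       train = vapply(seq_along(MODEL_IDS),
                                      function(k) stage_seed(ms, 10L + k),
                                      integer(1)),
                       importance = stage_seed(ms, 20L)),
    simulated = simulated,
    n_events = nrow(events), n_subjects_featurized = nrow(features),
    n_train = length(split$train), n_validation = length(split$validation))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(features = features, bundles = bundles,
                 predictions = pred_all, evaluation = evaluation,
                 model_comparison = model_cmp,
                 group_comparison = group_cmp, importance = imp,
                 ale_curves = curves, ale_surfaces = surfaces,
                 out_dir = out_dir))
}
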