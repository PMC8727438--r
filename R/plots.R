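#' Tuning-curve plot
#'
#' @param tuning_trace data.frame `mtry`, `cv_rmse` from [tune_mtry()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_tuning_curve <- function(tuning_trace, title = "mtry tuning") {
  ggplot2::ggplot(tuning_trace, ggplot2::aes(x = mtry, y = cv_rmse)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(title = title, x = "mtry (features per split)",
                  y = "CV RMSE (years)") +
    ggplot2::theme_minimal()
}

#' Feature-importance bar chart
#'
#' @param importance An `importance_table` from [permutation_importance()].
#' @param top_n Number of features shown (default 15).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 15) {
  df <- utils::head(as.data.frame(importance), top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = delta_mse, y = feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "Out-of-bag permutation importance",
                  x = expression(Delta ~ "OOB MSE (years"^2 * ")"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' ALE curve plot
#'
#' @param curve An `ale_curve`.
#' @return A ggplot object.
#' @export
plot_ale_curve <- function(curve) {
  df <- data.frame(x = curve$edges, effect = curve$effect)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = effect)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(title = paste("ALE:", curve$feature),
                  x = curve$feature, y = "Effect on predicted age (years)") +
    ggplot2::theme_minimal()
}

#' ALE interaction surface heat map
#'
#' @param surface An `ale_surface`.
#' @return A ggplot object.
#' @export
plot_ale_surface <- function(surface) {
  grid <- expand.grid(x = surface$edges1, y = surface$edges2)
  grid$value <- as.vector(surface$effect)
  ggplot2::ggplot(grid, ggplot2::aes(x = x, y = y, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = paste("ALE interaction:",
                                paste(surface$features, collapse = " x ")),
                  x = surface$features[1], y = surface$features[2],
                  fill = "years") +
    ggplot2::theme_minimal()
}

#' Prediction-error boxplots by screen status
#'
#' @param predictions data.frame from [predict_age()].
#' @return A ggplot object (raw and absolute error panels).
#' @export
plot_errors_by_mdq <- function(predictions) {
  long <- rbind(
    data.frame(group = ifelse(predictions$mdq_positive, "MDQ positive",
                              "MDQ negative"),
               value = predictions$raw_error, panel = "Raw error (years)"),
    data.frame(group = ifelse(predictions$mdq_positive, "MDQ positive",
                              "MDQ negative"),
               value = predictions$abs_error,
               panel = "Absolute error (years)"))
  ggplot2::ggplot(long, ggplot2::aes(x = group, y = value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Prediction error by screen status") +
    ggplot2::theme_minimal()
}

#' Render figures and a machine-readable summary
#'
#' Writes the interpretation and evaluation artifacts of a run: tuning
#' curves, importance bar chart, ALE curves and surfaces (PDF), error
#' boxplots, and a JSON summary covering the evaluation and group
#' comparison tables.
#'
#' @param out_dir Output directory (created if needed).
#' @param importance `importance_table` or `NULL`.
#' @param curves List of `ale_curve` objects (possibly empty).
#' @param surfaces List of `ale_surface` objects (possibly empty).
#' @param evaluation data.frame of evaluation rows.
#' @param group_comparison data.frame from [compare_groups_by_mdq()], or
#'   `NULL`.
#' @param predictions Prediction records for the boxplots, or `NULL`.
#' @param tuning_traces Named list of tuning-trace data.frames, or `NULL`.
#' @return Invisible character vector of files written.
#' @export
render_reports <- function(out_dir, importance = NULL, curves = list(),
                           surfaces = list(), evaluation = NULL,
                           group_comparison = NULL, predictions = NULL,
                           tuning_traces = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_plot <- function(p, name) {
    path <- file.path(out_dir, name)
    grDevices::pdf(path, width = 7, height = 5)
    print(p)
    grDevices::dev.off()
    written <<- c(written, path)
  }
  if (!is.null(tuning_traces)) {
    for (nm in names(tuning_traces)) {
      save_plot(plot_tuning_curve(tuning_traces[[nm]], paste("mtry tuning:", nm)),
                paste0("tuning_", nm, ".pdf"))
    }
  }
  if (!is.null(importance)) save_plot(plot_importance(importance),
                                      "importance.pdf")
  for (i in seq_along(curves)) {
    save_plot(plot_ale_curve(curves[[i]]),
              paste0("ale_", curves[[i]]$feature, ".pdf"))
  }
  for (i in seq_along(surfaces)) {
    save_plot(plot_ale_surface(surfaces[[i]]),
              paste0("ale2_", paste(surfaces[[i]]$features, collapse = "_"),
                     ".pdf"))
  }
  if (!is.null(predictions)) save_plot(plot_errors_by_mdq(predictions),
                                       "errors_by_mdq.pdf")
  summary <- list(
    evaluation = evaluation,
    group_comparison = group_comparison,
    importance = if (!is.null(importance)) as.data.frame(importance),
    ale_features = vapply(curves, function(cv) cv$feature, character(1)),
    ale_interactions = lapply(surfaces, function(s) s$features))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  written <- c(written, json_path)
  invisible(written)
}
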