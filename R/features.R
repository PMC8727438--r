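#' Canonical typing feature names
#'
#' The 30 typing features summarizing, for each of six session-level
#' series (keypress count, mean interkey time, median interkey time,
#' autocorrect rate, backspace rate, session length in seconds), the
#' across-session mean, median, sample standard deviation and unscaled
#' median absolute deviation (24 features), followed by the sample
#' entropy of each series (6 features). This order is the canonical
#' column order of every feature table produced by the package.
#'
#' @return Character vector of length 30.
#' @export
typing_feature_names <- function() {
  series <- c("keypresses_per_session", "interkey_time_mean",
              "interkey_time_median", "autocorrect_rate",
              "backspace_rate", "session_length")
  c(as.vector(t(outer(series, c("mean", "median", "sd", "mad"),
                      function(s, f) paste0(f, "_", s)))),
    paste0("sample_entropy_", series))
}

# session-level series underlying the features, in canonical order;
# maps feature-series label -> column of sessionize_log() output
.SERIES_COLS <- c(
  keypresses_per_session = "n_keypresses",
  interkey_time_mean     = "ikt_mean",
  interkey_time_median   = "ikt_median",
  autocorrect_rate       = "autocorrect_rate",
  backspace_rate         = "backspace_rate",
  session_length         = "duration"
)

#' Session-level metrics of a single session
#'
#' @param timestamps Sorted timestamps of the session (seconds).
#' @param event_types Character vector of event types, same length.
#' @return One-row data.frame with `n_keypresses`, `ikt_mean`,
#'   `ikt_median` (both missing for a single-keypress session),
#'   `autocorrect_rate`, `backspace_rate`, `duration`, `start_time`.
#' @export
session_metrics <- function(timestamps, event_types) {
  if (length(timestamps) == 0) stop("empty session")
  stopifnot(length(timestamps) == length(event_types))
  n <- length(timestamps)
  gaps <- diff(timestamps)
  data.frame(
    n_keypresses = n,
    ikt_mean = if (n >= 2) mean(gaps) else NA_real_,
    ikt_median = if (n >= 2) stats::median(gaps) else NA_real_,
    autocorrect_rate = mean(event_types == "autocorrect"),
    backspace_rate = mean(event_types == "backspace"),
    duration = timestamps[n] - timestamps[1],
    start_time = timestamps[1]
  )
}

#' Subject-level feature vector from per-session metrics
#'
#' Summarizes one subject's chronologically ordered session metrics into
#' the 30 typing features of [typing_feature_names()]. For each series,
#' missing elements are dropped before the four summaries (the interkey
#' series exclude single-keypress sessions); the standard deviation uses
#' the n-1 denominator and is missing for a length-1 series; the MAD is
#' unscaled. Sample entropy is computed on the chronologically ordered
#' series (it is the only order-sensitive feature) and is missing for
#' series shorter than `entropy$min_len`.
#'
#' @param session_metrics data.frame/data.table of one subject's sessions
#'   in chronological order, with the columns produced by
#'   [sessionize_log()].
#' @param entropy A [sampen_params()] object.
#' @return Named numeric vector of length 30.
#' @export
subject_features <- function(session_metrics, entropy = sampen_params()) {
  if (nrow(session_metrics) < 1) stop("subject has no sessions")
  sm <- as.data.frame(session_metrics)
  out <- numeric(0)
  for (lab in names(.SERIES_COLS)) {
    v <- as.numeric(sm[[.SERIES_COLS[[lab]]]])
    vv <- v[!is.na(v)]
    out[paste0("mean_", lab)] <- if (length(vv)) mean(vv) else NA_real_
    out[paste0("median_", lab)] <- if (length(vv)) stats::median(vv) else NA_real_
    out[paste0("sd_", lab)] <- if (length(vv) >= 2) stats::sd(vv) else NA_real_
    out[paste0("mad_", lab)] <- if (length(vv)) mad_unscaled(vv) else NA_real_
  }
  for (lab in names(.SERIES_COLS)) {
    v <- as.numeric(sm[[.SERIES_COLS[[lab]]]])
    vv <- v[!is.na(v)]
    out[paste0("sample_entropy_", lab)] <-
      if (length(vv) >= entropy$min_len) sample_entropy(vv, entropy) else NA_real_
  }
  out[typing_feature_names()]
}

#' Data-sufficiency inclusion filter
#'
#' Implements the "12 weeks worth of typing data" rule: the cohort median
#' daily keystroke rate is the median over subjects of (total keypresses
#' / days with any activity); a subject is included iff their total
#' keypress count is at least `min_weeks * 7` times that cohort median
#' (boundary equality includes).
#'
#' @param events Event table for the whole cohort.
#' @param min_weeks Minimum weeks of typical typing required (default 12).
#' @return A list with `included` (character vector of subject ids),
#'   `threshold` (keypress count), `cohort_median_daily`, and `report`, a
#'   data.frame per subject with totals, observed days and inclusion flag.
#' @export
filter_participants <- function(events, min_weeks = 12) {
  dt <- data.table::as.data.table(events)
  if (nrow(dt) == 0) stop("empty cohort: no events")
  per <- dt[, .(total = .N,
                days_observed = data.table::uniqueN(floor(timestamp / 86400))),
            by = subject_id]
  per[, daily_rate := total / days_observed]
  med_daily <- stats::median(per$daily_rate)
  threshold <- min_weeks * 7 * med_daily
  per[, included := total >= threshold]
  list(included = per[included == TRUE, subject_id],
       threshold = threshold,
       cohort_median_daily = med_daily,
       report = as.data.frame(per))
}

#' Compute the subject feature table for a cohort
#'
#' End-to-end featurization: tokenize events into sessions, optionally
#' apply the data-sufficiency filter, summarize each subject's sessions
#' into the 30 typing features, and join subject metadata (gender,
#' screen status, age). Age is derived from birth year against
#' `reference_year`, which defaults to the calendar year of the latest
#' event in the log.
#'
#' @param events Event table from [read_event_log()] or
#'   [generate_cohort()].
#' @param metadata Metadata data.frame from [read_metadata()] (age column
#'   optional; derived here when absent).
#' @param gap_threshold Session gap in seconds (default 5).
#' @param entropy A [sampen_params()] object.
#' @param min_weeks Inclusion threshold in weeks; `NULL` disables the
#'   filter.
#' @param reference_year Year for age derivation; default taken from the
#'   events.
#' @return data.frame with `subject_id`, the 30 typing features,
#'   `gender_not_male`, `mdq_positive`, `age`; one row per included
#'   subject that has metadata. Attribute `filter` carries the
#'   [filter_participants()] report when the filter was applied.
#' @export
compute_features <- function(events, metadata, gap_threshold = 5,
                             entropy = sampen_params(), min_weeks = 12,
                             reference_year = NULL) {
  dt <- data.table::as.data.table(events)
  if (nrow(dt) == 0) stop("empty event log")
  if (!("age" %in% names(metadata))) {
    reference_year <- reference_year %||% event_reference_year(dt)
    metadata <- finalize_ages(metadata, reference_year)
  }
  filt <- NULL
  if (!is.null(min_weeks)) {
    filt <- filter_participants(dt, min_weeks = min_weeks)
    dt <- dt[subject_id %in% filt$included]
    if (nrow(dt) == 0) stop("no subjects pass the inclusion filter")
  }
  sess <- sessionize_log(dt, gap_threshold = gap_threshold)
  data.table::setorder(sess, subject_id, session)
  feats <- sess[, as.list(subject_features(.SD, entropy = entropy)),
                by = subject_id]
  out <- merge(feats,
               data.table::as.data.table(
                 metadata[, c("subject_id", "gender_not_male",
                              "mdq_positive", "age")]),
               by = "subject_id")
  out <- as.data.frame(out)
  attr(out, "filter") <- filt
  out
}
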