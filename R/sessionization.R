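#' Tokenize a keystroke stream into typing sessions
#'
#' Groups consecutive keypresses of one subject into sessions: two
#' consecutive events belong to the same session when the difference of
#' their timestamps is strictly less than `gap_threshold` seconds. A gap
#' of exactly `gap_threshold` therefore starts a new session, and events
#' with identical timestamps always join. The result is the unique
#' maximal-run partition under this rule.
#'
#' @param timestamps Numeric vector of one subject's event times in
#'   seconds, sorted non-decreasingly. Unsorted input is a contract
#'   violation and raises an error rather than being silently re-sorted.
#' @param gap_threshold Session gap in seconds (default 5).
#' @return Integer vector of the same length: 1-based session index per
#'   event, non-decreasing. Length-0 input gives a length-0 result.
#' @export
tokenize_sessions <- function(timestamps, gap_threshold = 5) {
  stopifnot(is.numeric(timestamps), length(gap_threshold) == 1,
            gap_threshold > 0)
  n <- length(timestamps)
  if (n == 0) return(integer(0))
  if (any(!is.finite(timestamps))) stop("non-finite timestamp")
  d <- diff(timestamps)
  if (any(d < 0)) stop("timestamps must be sorted non-decreasingly")
  cumsum(c(1L, as.integer(d >= gap_threshold)))
}

#' Session time bounds
#'
#' @param timestamps Sorted timestamps of a single (non-empty) session.
#' @return A list with `start_time`, `end_time` and `duration`
#'   (`end - start`; 0 for a single-keypress session).
#' @export
session_bounds <- function(timestamps) {
  if (length(timestamps) == 0) stop("empty session")
  list(start_time = timestamps[1],
       end_time = timestamps[length(timestamps)],
       duration = timestamps[length(timestamps)] - timestamps[1])
}

#' Tokenize a multi-subject event log into per-session metrics
#'
#' Applies [tokenize_sessions()] within each subject and computes the six
#' session-level metrics used by the feature engine: keypress count, mean
#' and median interkey time (missing for single-keypress sessions),
#' autocorrect and backspace rates (computed over all keypress types),
#' and session duration.
#'
#' @param events Event table (`subject_id`, `timestamp`, `event_type`)
#'   sorted by subject then time, e.g. from [read_event_log()].
#' @param gap_threshold Session gap in seconds (default 5).
#' @return A `data.table` with one row per session: `subject_id`,
#'   `session`, `start_time`, `end_time`, `duration`, `n_keypresses`,
#'   `ikt_mean`, `ikt_median`, `autocorrect_rate`, `backspace_rate`,
#'   ordered chronologically within subject.
#' @export
sessionize_log <- function(events, gap_threshold = 5) {
  dt <- data.table::as.data.table(events)
  if (nrow(dt) == 0) {
    return(data.table::data.table(
      subject_id = character(0), session = integer(0),
      start_time = numeric(0), end_time = numeric(0), duration = numeric(0),
      n_keypresses = integer(0), ikt_mean = numeric(0),
      ikt_median = numeric(0), autocorrect_rate = numeric(0),
      backspace_rate = numeric(0)))
  }
  dt <- data.table::copy(dt)
  dt[, session := tokenize_sessions(timestamp, gap_threshold), by = subject_id]
  dt[, {
    gaps <- diff(timestamp)
    .(start_time = timestamp[1L],
      end_time = timestamp[.N],
      duration = timestamp[.N] - timestamp[1L],
      n_keypresses = .N,
      ikt_mean = if (.N >= 2L) mean(gaps) else NA_real_,
      ikt_median = if (.N >= 2L) stats::median(gaps) else NA_real_,
      autocorrect_rate = mean(event_type == "autocorrect"),
      backspace_rate = mean(event_type == "backspace"))
  }, by = .(subject_id, session)]
}
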