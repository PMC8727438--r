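#' Keypress event types
#'
#' The four event categories retained from keyboard metadata. Any other
#' label found in an input file is mapped to `"other"` (with a warning
#' reporting how many rows were remapped), so downstream rates are always
#' computed over a closed vocabulary.
#'
#' @export
EVENT_TYPES <- c("alphanumeric", "backspace", "autocorrect", "other")

# Timestamps larger than this are assumed to be milliseconds since epoch.
# 1e11 seconds is year ~5138, while 1e11 ms is 1973, so the magnitudes of
# the two encodings never overlap for plausible data.
.MS_THRESHOLD <- 1e11

#' Read a keystroke event log
#'
#' Reads a raw keypress event stream from CSV or JSON-lines. Each record
#' must carry `subject_id`, `timestamp` (seconds since epoch; inputs in
#' milliseconds are detected by magnitude and converted) and `event_type`.
#' Events are returned sorted by `(subject_id, timestamp)` with stable
#' order for tied timestamps. Unknown event-type labels are mapped to
#' `"other"`; rows with unparseable timestamps are rejected, never
#' silently dropped: the returned object carries accounting attributes so
#' that `input rows == kept events + rejected rows`.
#'
#' @param path Path to the input file.
#' @param format `"csv"` or `"jsonl"`. Defaults to guessing from the file
#'   extension.
#' @return A `data.table` with columns `subject_id` (character),
#'   `timestamp` (double, seconds) and `event_type` (character, one of
#'   [EVENT_TYPES]), sorted by subject then time. Attributes:
#'   `n_input_rows`, `n_rejected`, `n_unknown_type`, and `rejected` (a
#'   data.frame of rejected rows with `line` and `reason`).
#' @export
read_event_log <- function(path, format = c("guess", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    raw <- data.table::fread(path, colClasses = list(
      character = "subject_id"), showProgress = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    raw <- data.table::rbindlist(lapply(recs, function(r) {
      data.table::data.table(
        subject_id = as.character(r$subject_id %||% NA_character_),
        timestamp  = r$timestamp %||% NA,
        event_type = as.character(r$event_type %||% NA_character_)
      )
    }), fill = TRUE)
  }
  required <- c("subject_id", "timestamp", "event_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("event log schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  n_input <- nrow(raw)
  ts <- suppressWarnings(as.numeric(raw$timestamp))
  bad <- !is.finite(ts) | ts < 0
  rejected <- data.frame(line = which(bad),
                         reason = rep("unparseable or negative timestamp",
                                      sum(bad)))
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: unparseable or negative timestamp ",
            "(first at data row ", rejected$line[1], ")")
  }
  dt <- data.table::data.table(
    subject_id = as.character(raw$subject_id[!bad]),
    timestamp  = ts[!bad],
    event_type = as.character(raw$event_type[!bad])
  )
  # millisecond inputs: all (non-zero) timestamps enormous
  if (nrow(dt) > 0 && any(dt$timestamp > .MS_THRESHOLD)) {
    message("timestamps look like milliseconds since epoch; converting to seconds")
    dt[, timestamp := timestamp / 1000]
  }
  unknown <- !(dt$event_type %in% EVENT_TYPES)
  n_unknown <- sum(unknown)
  if (n_unknown > 0) {
    warning(n_unknown, " event(s) with unrecognized event_type mapped to 'other'")
    dt[unknown, event_type := "other"]
  }
  data.table::setorder(dt, subject_id, timestamp)  # stable for ties
  data.table::setattr(dt, "n_input_rows", n_input)
  data.table::setattr(dt, "n_rejected", sum(bad))
  data.table::setattr(dt, "n_unknown_type", n_unknown)
  data.table::setattr(dt, "rejected", rejected)
  dt[]
}

#' Write a keystroke event log
#'
#' @param events A data.frame/data.table with `subject_id`, `timestamp`,
#'   `event_type`.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  dt <- data.table::as.data.table(events)[, .(subject_id, timestamp, event_type)]
  if (format == "csv") {
    data.table::fwrite(dt, path)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(dt))) {
      writeLines(jsonlite::toJSON(as.list(dt[i]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  invisible(path)
}

#' Read a subject metadata table
#'
#' Reads the per-subject table (`subject_id`, `birth_year`, and optionally
#' `gender`, `mdq_score`, `self_report_dx`). The bipolar-disorder screen
#' is scored positive at an MDQ symptom score of 7 or more; subjects with
#' no score are flagged `unscreenable`. When `reference_year` is given,
#' chronological age is derived as `reference_year - birth_year` and
#' records with age outside \[18, 120\] are rejected with a warning (use
#' [finalize_ages()] to defer this until the observation window is known).
#'
#' @param path CSV path.
#' @param reference_year Integer year used to derive age, or `NULL` to
#'   defer age derivation.
#' @param mdq_cutoff Positive-screen threshold on the MDQ symptom score
#'   (default 7).
#' @return A data.frame with columns `subject_id`, `birth_year`,
#'   `gender` (`"male"`, `"not_male"` or `"missing"`), `gender_not_male`
#'   (0/1/NA), `mdq_score`, `mdq_positive`, `unscreenable`,
#'   `self_report_dx`, and `age` when `reference_year` was supplied.
#' @export
read_metadata <- function(path, reference_year = NULL, mdq_cutoff = 7L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, colClasses = list(character = "subject_id"),
                           showProgress = FALSE)
  required <- c("subject_id", "birth_year")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("metadata schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$subject_id)) {
    stop("duplicate subject_id in metadata: ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]),
               collapse = ", "))
  }
  meta <- data.frame(
    subject_id = as.character(raw$subject_id),
    birth_year = as.integer(raw$birth_year),
    stringsAsFactors = FALSE
  )
  gender <- if ("gender" %in% names(raw)) as.character(raw$gender) else
    rep(NA_character_, nrow(raw))
  gender[is.na(gender) | !nzchar(gender)] <- "missing"
  if (!all(gender %in% c("male", "not_male", "missing"))) {
    bad <- setdiff(unique(gender), c("male", "not_male", "missing"))
    stop("unrecognized gender label(s): ", paste(bad, collapse = ", "))
  }
  meta$gender <- gender
  meta$gender_not_male <- ifelse(gender == "missing", NA_real_,
                                 as.numeric(gender == "not_male"))
  score <- if ("mdq_score" %in% names(raw))
    suppressWarnings(as.integer(raw$mdq_score)) else rep(NA_integer_, nrow(raw))
  if (any(!is.na(score) & (score < 0 | score > 13))) {
    stop("mdq_score out of range [0, 13]")
  }
  meta$mdq_score <- score
  meta$mdq_positive <- ifelse(is.na(score), NA, score >= mdq_cutoff)
  meta$unscreenable <- is.na(score)
  meta$self_report_dx <- if ("self_report_dx" %in% names(raw)) {
    dx <- as.character(raw$self_report_dx)
    dx[is.na(dx) | !nzchar(dx)] <- "not_provided"
    dx
  } else rep("not_provided", nrow(raw))
  if (!is.null(reference_year)) {
    meta <- finalize_ages(meta, reference_year)
  }
  meta
}

#' Derive chronological age from birth year
#'
#' Age is `reference_year - birth_year`; records with age outside
#' \[18, 120\] are dropped with a warning. The default reference year in
#' the pipeline is the calendar year of the latest observed event.
#'
#' @param meta Metadata data.frame from [read_metadata()].
#' @param reference_year Integer year.
#' @return `meta` with an `age` column, implausible records removed.
#' @export
finalize_ages <- function(meta, reference_year) {
  age <- as.numeric(reference_year) - meta$birth_year
  bad <- !is.finite(age) | age < 18 | age > 120
  if (any(bad)) {
    warning(sum(bad), " metadata record(s) rejected: derived age outside [18, 120]")
  }
  meta <- meta[!bad, , drop = FALSE]
  meta$age <- age[!bad]
  rownames(meta) <- NULL
  meta
}

#' Reference year of an event log
#'
#' Calendar year (UTC) of the latest event; used as the default
#' `reference_year` for age derivation.
#'
#' @param events Event table with a `timestamp` column (seconds since epoch).
#' @return Integer year.
#' @export
event_reference_year <- function(events) {
  if (nrow(events) == 0) stop("empty event log")
  as.integer(format(as.POSIXct(max(events$timestamp),
                               origin = "1970-01-01", tz = "UTC"), "%Y"))
}

#' Write a subject feature table
#'
#' One row per subject: the 30 typing features in canonical order (see
#' [typing_feature_names()]) plus `gender_not_male`, `mdq_positive` and
#' `age`. Values are written with enough digits to round-trip losslessly
#' (15 significant digits); missing values become empty cells.
#'
#' @param features Feature table (data.frame), e.g. from
#'   [compute_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (nrow(features) == 0) stop("refusing to write an empty feature table")
  cols <- c("subject_id", typing_feature_names(),
            "gender_not_male", "mdq_positive", "age")
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- data.table::as.data.table(features)[, cols, with = FALSE]
  dt[, mdq_positive := as.numeric(mdq_positive)]
  data.table::fwrite(dt, path, na = "", scipen = 999)
  invisible(path)
}

#' Read a subject feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data.frame with `subject_id`, the 30 typing features,
#'   `gender_not_male`, `mdq_positive` (logical) and `age`.
#' @export
read_feature_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "subject_id"),
                          showProgress = FALSE, na.strings = c("", "NA"))
  df <- as.data.frame(dt)
  num_cols <- setdiff(names(df), "subject_id")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  if ("mdq_positive" %in% names(df)) df$mdq_positive <- df$mdq_positive > 0
  df
}
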