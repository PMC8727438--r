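#' Synthetic cohort parameters
#'
#' Parameters of the keystroke-stream simulator. Defaults emulate the
#' study conditions the analysis assumes: 344 subjects of whom 227/344
#' screen positive, ages 18-88, 84 days (~12 weeks) of observation, and
#' age effects with the qualitative shape the analysis is designed to
#' detect — interkey times and session lengths increasing with age, and
#' the session-to-session backspace-rate series becoming more regular
#' (lower sample entropy) with age. A scalar `brainage_offset_years`
#' (delta) is added to the *effective typing age* of screen-positive
#' subjects, the minimal mechanism for an accelerated-aging
#' (neuroprogression) signal.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param prop_mdq_positive Fraction screening positive (default 227/344).
#' @param age_range Integer years, `c(min, max)` (default 18-88).
#' @param n_days Observation days per subject (default 84).
#' @param sessions_per_day_rate Poisson mean sessions/day before the
#'   per-subject activity multiplier (default 6).
#' @param ikt_base Mean interkey time in seconds at the youngest age
#'   (default 0.22 s, typical mobile typing latency).
#' @param ikt_age_slope Added mean interkey seconds per year of effective
#'   typing age (default 0.004).
#' @param session_len_base Target mean session duration in seconds at the
#'   youngest age (default 20).
#' @param session_len_age_slope Added seconds of session duration per
#'   year (default 0.45).
#' @param backspace_rate_base Baseline backspace keypress fraction
#'   (default 0.12).
#' @param autocorrect_rate_base Baseline autocorrect fraction (default
#'   0.05).
#' @param entropy_age_effect In \[0, 1\]: maximum AR(1) persistence of the
#'   session-to-session backspace-rate signal, reached at the oldest age
#'   (default 0.85). Older subjects' series are smoother and more
#'   predictable, hence lower sample entropy.
#' @param brainage_offset_years Years added to the effective typing age
#'   of screen positives (default 0).
#' @param noise_sd_subject SD of the per-subject log interkey-time offset
#'   (default 0.15).
#' @param noise_sd_session SD of the per-session log interkey-time offset
#'   (default 0.1).
#' @param ikt_sdlog Keypress-level lognormal shape of interkey times
#'   (default 0.35).
#' @param activity_sdlog SD of the per-subject lognormal activity
#'   multiplier; produces the heavy-tailed total-keypress distribution
#'   typical of passive phone data (default 0.6).
#' @param prop_not_male Probability of `not_male` given screen status,
#'   `c(negative, positive)` (default `c(0.60, 0.75)`).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 344L,
                          prop_mdq_positive = 227 / 344,
                          age_range = c(18L, 88L),
                          n_days = 84L,
                          sessions_per_day_rate = 6,
                          ikt_base = 0.22,
                          ikt_age_slope = 0.004,
                          session_len_base = 20,
                          session_len_age_slope = 0.45,
                          backspace_rate_base = 0.12,
                          autocorrect_rate_base = 0.05,
                          entropy_age_effect = 0.85,
                          brainage_offset_years = 0,
                          noise_sd_subject = 0.15,
                          noise_sd_session = 0.1,
                          ikt_sdlog = 0.35,
                          activity_sdlog = 0.6,
                          prop_not_male = c(0.60, 0.75),
                          seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            prop_mdq_positive = prop_mdq_positive,
            age_range = as.integer(age_range), n_days = as.integer(n_days),
            sessions_per_day_rate = sessions_per_day_rate,
            ikt_base = ikt_base, ikt_age_slope = ikt_age_slope,
            session_len_base = session_len_base,
            session_len_age_slope = session_len_age_slope,
            backspace_rate_base = backspace_rate_base,
            autocorrect_rate_base = autocorrect_rate_base,
            entropy_age_effect = entropy_age_effect,
            brainage_offset_years = brainage_offset_years,
            noise_sd_subject = noise_sd_subject,
            noise_sd_session = noise_sd_session,
            ikt_sdlog = ikt_sdlog, activity_sdlog = activity_sdlog,
            prop_not_male = prop_not_male, seed = as.integer(seed))
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  if (p$n_subjects < 2) stop("cohort parameter error: n_subjects must be >= 2")
  if (p$prop_mdq_positive < 0 || p$prop_mdq_positive > 1)
    stop("cohort parameter error: prop_mdq_positive must be in [0, 1]")
  if (length(p$age_range) != 2 || p$age_range[1] >= p$age_range[2])
    stop("cohort parameter error: age_range must be an increasing pair")
  rates <- c(p$backspace_rate_base, p$autocorrect_rate_base,
             p$entropy_age_effect, p$prop_not_male)
  if (any(rates < 0 | rates > 1))
    stop("cohort parameter error: rates/fractions must be in [0, 1]")
  sds <- c(p$noise_sd_subject, p$noise_sd_session, p$ikt_sdlog,
           p$activity_sdlog)
  if (any(sds < 0)) stop("cohort parameter error: sd terms must be >= 0")
  if (p$n_days < 1) stop("cohort parameter error: n_days must be >= 1")
  if (p$sessions_per_day_rate < 0)
    stop("cohort parameter error: sessions_per_day_rate must be >= 0")
  invisible(TRUE)
}

# epoch of the simulated observation window: 2020-01-01 00:00 UTC, so
# derived ages use reference year 2020
.SIM_EPOCH <- 1577836800

#' Generate a synthetic cohort
#'
#' Draws subject profiles (age uniform over `age_range`, screen status
#' Bernoulli, MDQ scores consistent with status: 7-13 for positives, 0-6
#' for negatives) and simulates each subject's keystroke event stream
#' with [generate_subject_events()]. Screen positives type like someone
#' `brainage_offset_years` older (their *effective typing age*); their
#' chronological age and metadata are unaffected.
#'
#' @param params A [cohort_params()] object.
#' @return A list with `metadata` (as from [read_metadata()], with `age`),
#'   `events` (a `data.table` sorted by subject and time) and `profiles`
#'   (ground truth: `subject_id`, `true_age`, `effective_typing_age`,
#'   `mdq_positive`, `mdq_score`, `gender_not_male`, `n_sessions`, the
#'   generator's intended session count).
#' @export
generate_cohort <- function(params = cohort_params()) {
  validate_cohort_params(params)
  set.seed(params$seed)
  n <- params$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  true_age <- sample(seq(params$age_range[1], params$age_range[2]),
                     n, replace = TRUE)
  mdq_pos <- stats::rbinom(n, 1, params$prop_mdq_positive) == 1
  mdq_score <- ifelse(mdq_pos, sample(7:13, n, replace = TRUE),
                      sample(0:6, n, replace = TRUE))
  not_male <- stats::rbinom(n, 1,
                            ifelse(mdq_pos, params$prop_not_male[2],
                                   params$prop_not_male[1]))
  dx_probs <- list(negative = c(yes = 0.21, no = 0.56, not_provided = 0.23),
                   positive = c(yes = 0.51, no = 0.13, not_provided = 0.36))
  self_dx <- vapply(mdq_pos, function(pos) {
    pr <- if (pos) dx_probs$positive else dx_probs$negative
    sample(names(pr), 1, prob = pr)
  }, character(1))
  eff_age <- true_age + params$brainage_offset_years * mdq_pos

  profiles <- data.frame(
    subject_id = ids, true_age = true_age,
    effective_typing_age = eff_age, mdq_positive = mdq_pos,
    mdq_score = as.integer(mdq_score), gender_not_male = not_male,
    n_sessions = NA_integer_, stringsAsFactors = FALSE)

  ref_year <- 2020L
  metadata <- data.frame(
    subject_id = ids, birth_year = ref_year - true_age,
    gender = ifelse(not_male == 1, "not_male", "male"),
    gender_not_male = as.numeric(not_male),
    mdq_score = as.integer(mdq_score),
    mdq_positive = mdq_pos, unscreenable = FALSE,
    self_report_dx = self_dx, age = as.numeric(true_age),
    stringsAsFactors = FALSE)

  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- generate_subject_events(profiles[i, ], params)
    profiles$n_sessions[i] <- attr(ev, "n_sessions")
    ev_list[[i]] <- ev
  }
  events <- data.table::rbindlist(ev_list)
  data.table::setorder(events, subject_id, timestamp)
  list(metadata = metadata, events = events[], profiles = profiles)
}

#' Simulate one subject's keystroke event stream
#'
#' Sessions arrive by a per-day Poisson process (rate scaled by a
#' lognormal per-subject activity multiplier); successive sessions are
#' separated by at least 5 seconds by construction. Each session has a
#' geometric keypress count whose mean tracks the target session duration
#' for the subject's effective typing age; within-session interkey times
#' are lognormal with location increasing linearly in effective typing
#' age (truncated below 5 s so sessions never split); keypress types are
#' multinomial with a session-level backspace probability following an
#' AR(1) signal whose persistence increases with effective typing age
#' (driving the entropy-age effect).
#'
#' Uses the current RNG state; seed the stream (or call via
#' [generate_cohort()]) for reproducibility.
#'
#' @param profile One-row data.frame with `subject_id`,
#'   `effective_typing_age`.
#' @param params A [cohort_params()] object.
#' @return `data.table` of the subject's events, time-ordered, with
#'   attribute `n_sessions` (the intended session count).
#' @export
generate_subject_events <- function(profile, params = cohort_params()) {
  age0 <- params$age_range[1]
  age_span <- params$age_range[2] - params$age_range[1]
  eff <- profile$effective_typing_age

  act_mult <- stats::rlnorm(1, 0, params$activity_sdlog)
  subj_log_off <- stats::rnorm(1, 0, params$noise_sd_subject)
  ikt_mean_subj <- (params$ikt_base +
                      params$ikt_age_slope * (eff - age0)) * exp(subj_log_off)
  target_dur <- params$session_len_base +
    params$session_len_age_slope * (eff - age0)
  mean_kp <- max(2, 1 + target_dur / ikt_mean_subj)

  # backspace-rate signal: AR(1) on the logit scale, persistence growing
  # with effective typing age (older -> smoother -> lower sample entropy)
  rho <- params$entropy_age_effect *
    min(1, max(0, (eff - age0) / age_span))
  bs_logit0 <- stats::qlogis(min(max(params$backspace_rate_base, 1e-4),
                                 1 - 1e-4))
  ac_p <- params$autocorrect_rate_base
  other_p <- 0.02

  n_sess_day <- stats::rpois(params$n_days,
                             params$sessions_per_day_rate * act_mult)
  total_sessions <- sum(n_sess_day)
  if (total_sessions == 0) {
    out <- data.table::data.table(subject_id = character(0),
                                  timestamp = numeric(0),
                                  event_type = character(0))
    data.table::setattr(out, "n_sessions", 0L)
    return(out)
  }

  ts_list <- vector("list", total_sessions)
  ty_list <- vector("list", total_sessions)
  s_idx <- 0L
  prev_end <- -Inf
  w <- stats::rnorm(1, 0, 0.5)  # AR(1) state
  for (d in seq_len(params$n_days)) {
    k <- n_sess_day[d]
    if (k == 0) next
    day_start <- .SIM_EPOCH + (d - 1) * 86400 + stats::runif(1, 0, 43200)
    t0 <- max(day_start, prev_end + 5 + stats::rexp(1, 1 / 300))
    for (s in seq_len(k)) {
      s_idx <- s_idx + 1L
      if (s > 1) t0 <- prev_end + 5 + stats::rexp(1, 1 / 600)
      n_kp <- 1L + stats::rgeom(1, 1 / mean_kp)
      sess_off <- stats::rnorm(1, 0, params$noise_sd_session)
      if (n_kp >= 2) {
        mu <- log(ikt_mean_subj) + sess_off - params$ikt_sdlog^2 / 2
        gaps <- pmin(stats::rlnorm(n_kp - 1, mu, params$ikt_sdlog), 4.99)
        times <- t0 + cumsum(c(0, gaps))
      } else {
        times <- t0
      }
      w <- rho * w + stats::rnorm(1, 0, 0.4)
      bs_p <- stats::plogis(bs_logit0 + w)
      # keep the four type probabilities a proper simplex
      bs_p <- min(bs_p, 1 - ac_p - other_p - 0.05)
      types <- sample(EVENT_TYPES, n_kp, replace = TRUE,
                      prob = c(1 - bs_p - ac_p - other_p, bs_p, ac_p,
                               other_p))
      ts_list[[s_idx]] <- times
      ty_list[[s_idx]] <- types
      prev_end <- times[length(times)]
    }
  }
  out <- data.table::data.table(
    subject_id = profile$subject_id,
    timestamp = unlist(ts_list),
    event_type = unlist(ty_list))
  data.table::setattr(out, "n_sessions", as.integer(total_sessions))
  out
}
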