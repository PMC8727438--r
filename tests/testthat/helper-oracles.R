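# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written as plain loops over definitions,
# sharing no code with the implementation under test.

# split a sorted timestamp vector at every gap >= threshold
oracle_sessions <- function(ts, gap = 5) {
  n <- length(ts)
  if (n == 0) return(integer(0))
  id <- integer(n)
  cur <- 1L
  id[1] <- cur
  for (i in seq_len(n - 1)) {
    if (ts[i + 1] - ts[i] >= gap) cur <- cur + 1L
    id[i + 1] <- cur
  }
  id
}

# O(n^2) template-counting sample entropy
oracle_sampen <- function(x, m = 2, r_factor = 0.2, tau = 1, min_len = 10) {
  if (tau > 1) x <- x[seq(1, length(x), by = tau)]
  n <- length(x)
  if (n < min_len) return(NA_real_)
  r <- r_factor * sd(x)
  np <- n - m
  if (np < 2) return(NA_real_)
  A <- 0L; B <- 0L
  for (i in 1:(np - 1)) {
    for (j in (i + 1):np) {
      dmax_m <- 0
      for (k in 0:(m - 1)) {
        dmax_m <- max(dmax_m, abs(x[i + k] - x[j + k]))
      }
      if (dmax_m <= r) {
        B <- B + 1L
        if (max(dmax_m, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# straight-line recomputation of the 30 typing features from a session
# metrics table (chronological order assumed)
oracle_subject_features <- function(sess, entropy = sampen_params()) {
  cols <- c(keypresses_per_session = "n_keypresses",
            interkey_time_mean = "ikt_mean",
            interkey_time_median = "ikt_median",
            autocorrect_rate = "autocorrect_rate",
            backspace_rate = "backspace_rate",
            session_length = "duration")
  out <- numeric(0)
  for (lab in names(cols)) {
    v <- sess[[cols[[lab]]]]
    v <- v[!is.na(v)]
    out[paste0("mean_", lab)] <- mean(v)
    out[paste0("median_", lab)] <- median(v)
    out[paste0("sd_", lab)] <- if (length(v) >= 2) sd(v) else NA_real_
    out[paste0("mad_", lab)] <- median(abs(v - median(v)))
  }
  for (lab in names(cols)) {
    v <- sess[[cols[[lab]]]]
    v <- v[!is.na(v)]
    out[paste0("sample_entropy_", lab)] <-
      if (length(v) >= entropy$min_len)
        oracle_sampen(v, entropy$m, entropy$r_factor, entropy$tau,
                      entropy$min_len)
      else NA_real_
  }
  out[typing_feature_names()]
}

# loop-based first-order ALE over quantile bins
oracle_ale1 <- function(predict_fn, data, feature, n_bins) {
  x <- data[[feature]]
  edges <- unique(quantile(x, seq(0, 1, length.out = n_bins + 1),
                           names = FALSE))
  K <- length(edges) - 1
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  delta <- numeric(K)
  counts <- integer(K)
  for (k in 1:K) {
    rows <- which(bin == k)
    counts[k] <- length(rows)
    if (length(rows) == 0) next
    d_hi <- data[rows, , drop = FALSE]; d_hi[[feature]] <- edges[k + 1]
    d_lo <- data[rows, , drop = FALSE]; d_lo[[feature]] <- edges[k]
    delta[k] <- mean(predict_fn(d_hi) - predict_fn(d_lo))
  }
  fj <- c(0, cumsum(delta))
  mids <- (fj[1:K] + fj[2:(K + 1)]) / 2
  fj - sum(counts * mids) / sum(counts)
}

# loop-based second-order ALE (no empty cells assumed)
oracle_ale2 <- function(predict_fn, data, features, n_bins) {
  x1 <- data[[features[1]]]; x2 <- data[[features[2]]]
  e1 <- unique(quantile(x1, seq(0, 1, length.out = n_bins + 1), names = FALSE))
  e2 <- unique(quantile(x2, seq(0, 1, length.out = n_bins + 1), names = FALSE))
  K1 <- length(e1) - 1; K2 <- length(e2) - 1
  b1 <- findInterval(x1, e1, rightmost.closed = TRUE, all.inside = TRUE)
  b2 <- findInterval(x2, e2, rightmost.closed = TRUE, all.inside = TRUE)
  n <- nrow(data)
  delta <- matrix(NA_real_, K1, K2)
  counts <- matrix(0L, K1, K2)
  for (j in 1:K1) for (k in 1:K2) {
    rows <- which(b1 == j & b2 == k)
    counts[j, k] <- length(rows)
    if (length(rows) == 0) next
    f_at <- function(v1, v2) {
      d <- data[rows, , drop = FALSE]
      d[[features[1]]] <- v1; d[[features[2]]] <- v2
      predict_fn(d)
    }
    delta[j, k] <- mean(f_at(e1[j + 1], e2[k + 1]) - f_at(e1[j], e2[k + 1]) -
                          f_at(e1[j + 1], e2[k]) + f_at(e1[j], e2[k]))
  }
  stopifnot(!anyNA(delta))  # oracle only used on data covering all cells
  H <- matrix(0, K1 + 1, K2 + 1)
  for (j in 1:K1) for (k in 1:K2) {
    H[j + 1, k + 1] <- sum(delta[1:j, 1:k])
  }
  # first-order components implied by the accumulated surface
  f1 <- numeric(K1 + 1)
  for (j in 1:K1) {
    num <- 0
    for (k in 1:K2) {
      num <- num + counts[j, k] *
        ((H[j + 1, k] - H[j, k]) + (H[j + 1, k + 1] - H[j, k + 1])) / 2
    }
    f1[j + 1] <- f1[j] + num / max(sum(counts[j, ]), 1)
  }
  f2 <- numeric(K2 + 1)
  for (k in 1:K2) {
    num <- 0
    for (j in 1:K1) {
      num <- num + counts[j, k] *
        ((H[j, k + 1] - H[j, k]) + (H[j + 1, k + 1] - H[j + 1, k])) / 2
    }
    f2[k + 1] <- f2[k] + num / max(sum(counts[, k]), 1)
  }
  for (j in 1:(K1 + 1)) for (k in 1:(K2 + 1)) {
    H[j, k] <- H[j, k] - f1[j] - f2[k]
  }
  f0 <- 0
  for (j in 1:K1) for (k in 1:K2) {
    f0 <- f0 + counts[j, k] *
      (H[j, k] + H[j + 1, k] + H[j, k + 1] + H[j + 1, k + 1]) / 4
  }
  H - f0 / n
}

# small simulated cohort shared across tests
make_test_cohort <- function(n_subjects = 30, n_days = 7, rate = 3,
                             seed = 42, ...) {
  generate_cohort(cohort_params(n_subjects = n_subjects, n_days = n_days,
                                sessions_per_day_rate = rate, seed = seed,
                                ...))
}

# random event stream with mixed gap scales for tokenizer tests
random_stream <- function(n, gap_scale = c(0.5, 2, 6, 20)) {
  if (n == 0) return(numeric(0))
  gaps <- sample(c(runif(n, 0, 4.9), runif(n, 4, 8), rexp(n, 1 / 15)), n)
  cumsum(c(runif(1, 0, 10), gaps[seq_len(n - 1)]))
}
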