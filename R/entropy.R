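#' Sample entropy parameters
#'
#' Parameters of the sample-entropy estimator applied to the session-level
#' series: embedding length `m`, tolerance `r = r_factor * sd(series)`,
#' subsampling stride `tau`, and the minimum (post-stride) series length
#' below which the estimate is reported as missing.
#'
#' @param m Embedding (template) length, default 2.
#' @param r_factor Tolerance as a multiple of the series standard
#'   deviation, default 0.2.
#' @param tau Subsampling stride, default 1 (use every point).
#' @param min_len Minimum series length for a defined estimate, default
#'   10. `m = 2` needs at least 4 points to be defined at all; 10 guards
#'   against wild small-sample estimates.
#' @return A list of class `sampen_params`.
#' @export
sampen_params <- function(m = 2L, r_factor = 0.2, tau = 1L, min_len = 10L) {
  stopifnot(m >= 1, r_factor > 0, tau >= 1, min_len >= m + 2)
  structure(list(m = as.integer(m), r_factor = r_factor,
                 tau = as.integer(tau), min_len = as.integer(min_len)),
            class = "sampen_params")
}

#' Sample entropy of a numeric series
#'
#' SampEn = -ln(A/B), where B counts pairs of length-`m` templates whose
#' Chebyshev distance is at most `r = r_factor * sd(x)` and A counts the
#' same for length-`m + 1` templates. Self-matches are excluded; both
#' counts run over template start points `1 .. n - m` so every length-`m`
#' template has a length-`m + 1` extension (the Richman-Moorman
#' convention). Because `r` is tied to the series standard deviation, the
#' estimate is invariant under affine transforms `a*x + b` with `a > 0`.
#'
#' A constant series gives 0 (all templates match at any `r >= 0`).
#' The result is missing when the (post-stride) series is shorter than
#' `min_len` or when either template count is zero, keeping the estimator
#' finite.
#'
#' @param x Numeric series in chronological order.
#' @param params A [sampen_params()] object.
#' @return A single double, or `NA` when undefined.
#' @export
sample_entropy <- function(x, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  if (length(x) > 0 && any(!is.finite(x))) {
    stop("sample_entropy: series contains non-finite values")
  }
  if (params$tau > 1L) x <- x[seq(1L, length(x), by = params$tau)]
  n <- length(x)
  if (n < params$min_len) return(NA_real_)
  m <- params$m
  np <- n - m  # number of templates considered (both orders)
  if (np < 2L) return(NA_real_)
  r <- params$r_factor * stats::sd(x)
  # pairwise Chebyshev distances between length-m templates, built up one
  # coordinate at a time
  dm <- matrix(0, np, np)
  for (k in 0:(m - 1L)) {
    seg <- x[(1L + k):(np + k)]
    dm <- pmax(dm, abs(outer(seg, seg, "-")))
  }
  seg <- x[(1L + m):(np + m)]
  dm1 <- pmax(dm, abs(outer(seg, seg, "-")))
  ut <- upper.tri(dm)
  B <- sum(dm[ut] <= r)
  A <- sum(dm1[ut] <= r)
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

#' Unscaled median absolute deviation
#'
#' `median(|x - median(x)|)` with no consistency factor. Note this
#' deliberately differs from [stats::mad()]'s default, which multiplies
#' by 1.4826 to be consistent for the normal distribution; the feature
#' set uses the raw robust spread.
#'
#' @param x Non-empty numeric vector (missing values dropped).
#' @return A single double.
#' @export
mad_unscaled <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("mad_unscaled: empty input")
  stats::mad(x, constant = 1)
}
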