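toy_data <- function(n = 40, seed = 1, p = 3) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n))
  names(d) <- paste0("x", seq_len(p))
  d
}

test_that("an ignored feature has an identically zero ALE curve", {
  d <- toy_data(50)
  curve <- ale_first_order(function(dd) dd$x2 * 3, d, "x1", n_bins = 8)
  expect_equal(curve$effect, rep(0, length(curve$effect)))
})

test_that("ALE of a linear predictor recovers the slope exactly", {
  # induce strong correlation between features: the property that breaks
  # partial dependence but not ALE
  d <- toy_data(60, seed = 2)
  d$x2 <- d$x1 + rnorm(60, 0, 0.05)
  a <- 3.7
  curve <- ale_first_order(function(dd) a * dd$x1 + 5 * dd$x2, d, "x1",
                           n_bins = 10)
  slopes <- diff(curve$effect) / diff(curve$edges)
  expect_equal(slopes, rep(a, length(slopes)), tolerance = 1e-8)
  # centering identity: count-weighted mean of interpolated effects is 0
  K <- length(curve$counts)
  mids <- (curve$effect[1:K] + curve$effect[2:(K + 1)]) / 2
  expect_equal(sum(curve$counts * mids) / sum(curve$counts), 0,
               tolerance = 1e-8)
})

test_that("ALE curves match a brute-force oracle on a toy forest", {
  d <- toy_data(40, seed = 3)
  y <- d$x1^2 + d$x2 + rnorm(40, 0, 0.1)
  set.seed(4)
  rf <- randomForest::randomForest(d, y, ntree = 50)
  pf <- function(dd) as.numeric(predict(rf, dd))
  curve <- ale_first_order(pf, d, "x1", n_bins = 5)
  expect_equal(curve$effect, oracle_ale1(pf, d, "x1", 5), tolerance = 1e-8)
})

test_that("a constant feature is rejected", {
  d <- toy_data(20)
  d$x1 <- 1
  expect_error(ale_first_order(function(dd) dd$x2, d, "x1"), "constant")
})

test_that("additive predictors have an identically zero ALE surface", {
  d <- toy_data(60, seed = 5)
  s <- ale_second_order(function(dd) sin(dd$x1) + dd$x2^2, d,
                        c("x1", "x2"), n_bins = 4)
  expect_equal(max(abs(s$effect)), 0, tolerance = 1e-8)
})

test_that("the surface of f = x1*x2 carries the closed-form interaction", {
  d <- toy_data(80, seed = 6)
  s <- ale_second_order(function(dd) dd$x1 * dd$x2, d, c("x1", "x2"),
                        n_bins = 4)
  # doubly-centered surface equals z1*z2 up to additive row/col terms:
  # its second differences must match exactly
  K1 <- length(s$edges1) - 1; K2 <- length(s$edges2) - 1
  for (j in 1:K1) for (k in 1:K2) {
    got <- s$effect[j + 1, k + 1] - s$effect[j, k + 1] -
      s$effect[j + 1, k] + s$effect[j, k]
    want <- (s$edges1[j + 1] - s$edges1[j]) * (s$edges2[k + 1] - s$edges2[k])
    expect_equal(got, want, tolerance = 1e-6)
  }
  # doubly-centered: count-weighted corner means vanish
  corner_mean <- sum(s$counts * (s$effect[1:K1, 1:K2] +
                                   s$effect[2:(K1 + 1), 1:K2] +
                                   s$effect[1:K1, 2:(K2 + 1)] +
                                   s$effect[2:(K1 + 1), 2:(K2 + 1)]) / 4) /
    sum(s$counts)
  expect_equal(corner_mean, 0, tolerance = 1e-8)
})

test_that("ALE surfaces match a brute-force oracle on a toy forest", {
  d <- toy_data(30, seed = 7, p = 2)
  y <- d$x1 * d$x2 + rnorm(30, 0, 0.1)
  set.seed(8)
  rf <- randomForest::randomForest(d, y, ntree = 40)
  pf <- function(dd) as.numeric(predict(rf, dd))
  s <- ale_second_order(pf, d, c("x1", "x2"), n_bins = 3)
  expect_equal(s$effect, oracle_ale2(pf, d, c("x1", "x2"), 3),
               tolerance = 1e-8)
})

fit_toy_bundle <- function(n = 80, seed = 9, dup = FALSE) {
  set.seed(seed)
  f <- data.frame(signal = rnorm(n), noise = rnorm(n))
  if (dup) f$signal2 <- f$signal
  y <- 5 * f$signal + rnorm(n, 0, 0.5)
  forest <- randomForest::randomForest(f, y, ntree = 100, keep.inbag = TRUE,
                                       keep.forest = TRUE)
  structure(list(model_id = "toy", forest = forest,
                 feature_names = names(f),
                 imputation_values = vapply(f, median, numeric(1)),
                 train_x = f, train_y = y),
            class = "age_model_bundle")
}

test_that("the identity permutation yields exactly zero importance", {
  b <- fit_toy_bundle()
  n <- nrow(b$train_x)
  base <- typeage:::oob_mse_permuted(b, "signal", seq_len(n))
  expect_identical(typeage:::oob_mse_permuted(b, "signal", seq_len(n)) - base,
                   0)
})

test_that("importance separates signal from label-independent noise", {
  b <- fit_toy_bundle(n = 120, seed = 10)
  imp <- permutation_importance(b, seed = 11, n_permutations = 5)
  s <- imp$delta_mse[imp$feature == "signal"]
  z <- imp$delta_mse[imp$feature == "noise"]
  expect_gt(s, 10 * abs(z))
  expect_lt(abs(z), 1)  # converges to 0; tolerance at this n
  expect_setequal(imp$rank, 1:2)
  expect_equal(imp$feature[imp$rank == 1], "signal")
})

test_that("duplicating the strongest feature shares its credit", {
  b1 <- fit_toy_bundle(n = 120, seed = 12)
  b2 <- fit_toy_bundle(n = 120, seed = 12, dup = TRUE)
  i1 <- permutation_importance(b1, seed = 13)
  i2 <- permutation_importance(b2, seed = 13)
  single <- i1$delta_mse[i1$feature == "signal"]
  shared <- i2$delta_mse[i2$feature %in% c("signal", "signal2")]
  expect_true(all(shared < single))
  # model quality itself barely changes: baseline OOB MSE stays small
  # relative to the target variance
  base1 <- attr(i1, "baseline_oob_mse")
  base2 <- attr(i2, "baseline_oob_mse")
  expect_lt(abs(base1 - base2), 0.1 * var(b1$train_y))
})

test_that("a forest without in-bag records is rejected", {
  set.seed(14)
  f <- data.frame(a = rnorm(30))
  forest <- randomForest::randomForest(f, rnorm(30), ntree = 20)
  b <- structure(list(forest = forest, feature_names = "a", train_x = f,
                      train_y = rnorm(30)), class = "age_model_bundle")
  expect_error(permutation_importance(b), "in-bag")
})

test_that("render_reports writes figures and a complete JSON summary", {
  d <- toy_data(40, seed = 15)
  y <- d$x1 + rnorm(40, 0.2)
  set.seed(16)
  rf <- randomForest::randomForest(d, y, ntree = 30)
  pf <- function(dd) as.numeric(predict(rf, dd))
  curve <- ale_first_order(pf, d, "x1", n_bins = 5)
  ev <- data.frame(model_id = "m", partition = "validation", n = 40,
                   rmse = 1, pseudo_r2 = 0.5, median_abs_error = 0.7)
  pred <- data.frame(raw_error = rnorm(20), abs_error = abs(rnorm(20)),
                     mdq_positive = rep(c(TRUE, FALSE), 10))
  gc <- compare_groups_by_mdq(pred)
  out <- withr::local_tempdir()
  files <- render_reports(out, importance = NULL, curves = list(curve),
                          surfaces = list(), evaluation = ev,
                          group_comparison = gc, predictions = pred)
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_false(any(grepl("^ale2_", basename(list.files(out)))))
  expect_true(any(grepl("^ale_x1", basename(list.files(out)))))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_true(all(c("evaluation", "group_comparison") %in% names(js)))
  expect_true(all(c("rmse", "pseudo_r2", "median_abs_error") %in%
                    names(js$evaluation[[1]])))
  expect_true(all(c("statistic", "p_raw", "p_adjusted") %in%
                    names(js$group_comparison[[1]])))
})
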