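make_feature_fixture <- function(n = 60, seed = 99, signal = TRUE) {
  set.seed(seed)
  feats <- as.data.frame(matrix(rnorm(n * 30), n))
  names(feats) <- typing_feature_names()
  feats$gender_not_male <- rbinom(n, 1, 0.7)
  feats$mdq_positive <- rbinom(n, 1, 0.66) == 1
  feats$age <- if (signal) {
    round(25 + 20 * feats$mean_interkey_time_mean + rnorm(n, 0, 2)) + 20
  } else sample(18:80, n, replace = TRUE)
  feats$subject_id <- sprintf("s%03d", seq_len(n))
  feats
}

test_that("the 75:25 split follows the ceiling rule and is seeded", {
  ids <- sprintf("s%03d", 1:344)
  sp <- split_train_validation(ids, 0.75, seed = 1)
  expect_length(sp$train, 258)
  expect_length(sp$validation, 86)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ids)

  sp9 <- split_train_validation(ids[1:9], 0.75, seed = 1)
  expect_length(sp9$train, 7)  # ceiling(6.75)

  expect_identical(split_train_validation(ids, seed = 5),
                   split_train_validation(ids, seed = 5))
  expect_false(identical(split_train_validation(ids, seed = 5)$train,
                         split_train_validation(ids, seed = 6)$train))
  expect_error(split_train_validation(ids[1:4]), "too few")
})

test_that("a single-candidate grid is chosen trivially", {
  f <- make_feature_fixture(n = 40)
  x <- f[, typing_feature_names()]
  tuned <- tune_mtry(x, f$age,
                     tune_config(mtry_grid = 7, cv_folds = 3,
                                 cv_repeats = 1, n_trees = 30, seed = 2))
  expect_equal(tuned$chosen_mtry, 7)
  expect_equal(nrow(tuned$tuning_trace), 1)
})

test_that("grid values exceeding the predictor count are skipped", {
  f <- make_feature_fixture(n = 30)
  x <- f[, typing_feature_names()[1:5]]
  expect_warning(
    tuned <- tune_mtry(x, f$age,
                       tune_config(mtry_grid = c(2, 40), cv_folds = 3,
                                   cv_repeats = 1, n_trees = 20, seed = 3)),
    "skipping")
  expect_equal(tuned$tuning_trace$mtry, 2)
})

test_that("tuning with signal beats the null predictor", {
  f <- make_feature_fixture(n = 80, seed = 13)
  x <- f[, typing_feature_names()]
  tuned <- tune_mtry(x, f$age,
                     tune_config(mtry_grid = c(5, 15), cv_folds = 4,
                                 cv_repeats = 1, n_trees = 60, seed = 4))
  expect_true(min(tuned$tuning_trace$cv_rmse) < sd(f$age))
})

test_that("a constant target yields constant predictions", {
  f <- make_feature_fixture(n = 30)
  x <- f[, typing_feature_names()]
  b <- suppressWarnings(
    fit_age_model(x, rep(42, 30), "model1_typing_only", chosen_mtry = 5,
                  config = tune_config(mtry_grid = 5, n_trees = 30,
                                       seed = 5)))
  f$age <- 1  # irrelevant
  pred <- predict_age(b, f)
  expect_equal(pred$age_pred, rep(42, 30))
})

test_that("model bundles store leakage-free imputation and predictor sets", {
  f <- make_feature_fixture(n = 50, seed = 7)
  f$sample_entropy_backspace_rate[1:10] <- NA
  cfg <- tune_config(mtry_grid = 5, cv_folds = 3, cv_repeats = 1,
                     n_trees = 40, seed = 6)
  b1 <- train_age_model(f, "model1_typing_only", cfg)
  b2 <- train_age_model(f, "model2_plus_gender_mdq", cfg)
  expect_length(b1$feature_names, 30)
  expect_length(b2$feature_names, 32)
  expect_setequal(setdiff(b2$feature_names, b1$feature_names),
                  c("gender_not_male", "mdq_positive"))
  expect_equal(unname(b1$imputation_values["sample_entropy_backspace_rate"]),
               median(f$sample_entropy_backspace_rate, na.rm = TRUE))
  expect_equal(b1$chosen_mtry,
               b1$tuning_trace$mtry[which.min(b1$tuning_trace$cv_rmse)])

  # all-missing feature is an error naming the feature
  f2 <- make_feature_fixture(n = 30)
  f2$mad_session_length <- NA_real_
  expect_error(train_age_model(f2, "model1_typing_only", cfg),
               "mad_session_length")
})

test_that("prediction is order-invariant and tolerates all-missing rows", {
  f <- make_feature_fixture(n = 40, seed = 8)
  cfg <- tune_config(mtry_grid = 5, cv_folds = 3, cv_repeats = 1,
                     n_trees = 40, seed = 9)
  b <- train_age_model(f, "model1_typing_only", cfg)
  p1 <- predict_age(b, f)
  set.seed(10)
  shuffled <- f[sample(nrow(f)), ]
  p2 <- predict_age(b, shuffled)
  m <- match(p1$subject_id, p2$subject_id)
  expect_equal(p1$age_pred, p2$age_pred[m])
  expect_equal(p1$raw_error, p1$age_pred - p1$age_true)
  expect_equal(p1$abs_error, abs(p1$raw_error))

  # subject with every feature missing is predicted from the median vector
  ghost <- f[1, ]
  ghost[typing_feature_names()] <- NA_real_
  ghost$subject_id <- "ghost"
  expect_no_error(pg <- predict_age(b, ghost))
  expect_true(is.finite(pg$age_pred))

  expect_error(predict_age(b, f[, 1:10]), "schema")
})

test_that("the fitted pipeline is deterministic under a fixed seed", {
  f <- make_feature_fixture(n = 40, seed = 11)
  cfg <- tune_config(mtry_grid = c(3, 8), cv_folds = 3, cv_repeats = 1,
                     n_trees = 40, seed = 12)
  b1 <- train_age_model(f, "model1_typing_only", cfg)
  b2 <- train_age_model(f, "model1_typing_only", cfg)
  expect_identical(b1$chosen_mtry, b2$chosen_mtry)
  expect_equal(predict_age(b1, f)$age_pred, predict_age(b2, f)$age_pred)
})
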