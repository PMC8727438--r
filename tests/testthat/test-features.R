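test_that("session metrics follow their definitions", {
  m <- session_metrics(c(0, 0.2, 0.4), rep("alphanumeric", 3))
  expect_equal(m$n_keypresses, 3)
  expect_equal(m$ikt_mean, 0.2)
  expect_equal(m$ikt_median, 0.2)
  expect_equal(m$autocorrect_rate, 0)
  expect_equal(m$backspace_rate, 0)
  expect_equal(m$duration, 0.4)

  m2 <- session_metrics(0:3, c("alphanumeric", "backspace", "autocorrect",
                               "alphanumeric"))
  expect_equal(m2$backspace_rate, 0.25)
  expect_equal(m2$autocorrect_rate, 0.25)

  m3 <- session_metrics(5.0, "backspace")
  expect_equal(m3$n_keypresses, 1)
  expect_true(is.na(m3$ikt_mean) && is.na(m3$ikt_median))
  expect_equal(m3$backspace_rate, 1)
  expect_equal(m3$duration, 0)
  expect_error(session_metrics(numeric(0), character(0)), "empty")
})

test_that("there are exactly 30 typing features and 32 Model-2 predictors", {
  expect_length(typing_feature_names(), 30)
  expect_false(anyDuplicated(typing_feature_names()) > 0)
  expect_length(model_predictors("model1_typing_only"), 30)
  expect_length(model_predictors("model2_plus_gender_mdq"), 32)
  expect_setequal(setdiff(model_predictors("model2_plus_gender_mdq"),
                          model_predictors("model1_typing_only")),
                  c("gender_not_male", "mdq_positive"))
})

test_that("degenerate subjects give zero dispersion and missing entropy", {
  sess <- data.frame(n_keypresses = c(5, 5), ikt_mean = c(0.2, 0.2),
                     ikt_median = c(0.2, 0.2), autocorrect_rate = c(0, 0),
                     backspace_rate = c(0.2, 0.2), duration = c(1, 1))
  f <- subject_features(sess)
  sd_mad <- grepl("^(sd|mad)_", names(f))
  expect_true(all(f[sd_mad] == 0))
  expect_true(all(is.na(f[grepl("^sample_entropy", names(f))])))
})

test_that("mean and median summaries coincide for symmetric series", {
  sess <- data.frame(n_keypresses = c(2, 4, 6), ikt_mean = c(0.1, 0.2, 0.3),
                     ikt_median = c(0.1, 0.2, 0.3),
                     autocorrect_rate = c(0, 0.1, 0.2),
                     backspace_rate = c(0.1, 0.2, 0.3),
                     duration = c(1, 2, 3))
  f <- subject_features(sess)
  expect_equal(f[["mean_keypresses_per_session"]],
               f[["median_keypresses_per_session"]])
  expect_equal(f[["mean_session_length"]], f[["median_session_length"]])
})

test_that("features match a straight-line recomputation on a seeded subject", {
  co <- make_test_cohort(n_subjects = 2, n_days = 20, rate = 5, seed = 19)
  sess <- sessionize_log(co$events)
  for (s in unique(sess$subject_id)) {
    st <- as.data.frame(sess[sess$subject_id == s, ])
    expect_equal(subject_features(st), oracle_subject_features(st),
                 tolerance = 1e-10)
  }
})

test_that("only the entropy features are order-sensitive", {
  co <- make_test_cohort(n_subjects = 2, n_days = 20, rate = 5, seed = 21)
  st <- as.data.frame(sessionize_log(co$events))
  st <- st[st$subject_id == st$subject_id[1], ]
  f1 <- subject_features(st)
  set.seed(22)
  f2 <- subject_features(st[sample(nrow(st)), ])
  ent <- grepl("^sample_entropy", names(f1))
  expect_equal(f1[!ent], f2[!ent])
  expect_false(isTRUE(all.equal(f1[ent], f2[ent])))
})

test_that("rate features lie in [0,1] and dispersion features are >= 0", {
  co <- make_test_cohort(n_subjects = 10, seed = 25)
  feats <- compute_features(co$events, co$metadata, min_weeks = NULL)
  rate_cols <- grep("(autocorrect|backspace)_rate$", typing_feature_names(),
                    value = TRUE)
  rate_cols <- grep("^(mean|median)_", rate_cols, value = TRUE)
  for (cl in rate_cols) {
    expect_true(all(feats[[cl]] >= 0 & feats[[cl]] <= 1, na.rm = TRUE))
  }
  disp <- unlist(feats[grepl("^(sd|mad|sample_entropy)_", names(feats))])
  expect_true(all(disp >= 0, na.rm = TRUE))
})

test_that("the inclusion filter implements the cohort-median-daily rule", {
  # two planted activity halves: hand computation
  mk <- function(id, n_per_day, days) {
    data.frame(subject_id = id,
               timestamp = as.vector(vapply(seq_len(days) - 1, function(d) {
                 d * 86400 + seq(0, by = 10, length.out = n_per_day)
               }, numeric(n_per_day))),
               event_type = "alphanumeric")
  }
  ev <- rbind(mk("hi1", 100, 84), mk("hi2", 100, 84),
              mk("lo1", 10, 84), mk("lo2", 10, 84), mk("lo3", 2, 10))
  res <- filter_participants(ev, min_weeks = 12)
  # cohort median daily rate = median(100,100,10,10,2) = 10
  expect_equal(res$cohort_median_daily, 10)
  expect_equal(res$threshold, 84 * 10)
  # hi*: 8400 >= 840; lo1/lo2: 840 >= 840 boundary-included; lo3: 20 < 840
  expect_setequal(res$included, c("hi1", "hi2", "lo1", "lo2"))

  # identical activity across subjects with a full window: all included
  ev2 <- rbind(mk("a", 50, 84), mk("b", 50, 84), mk("c", 50, 84))
  expect_setequal(filter_participants(ev2)$included, c("a", "b", "c"))
  expect_error(filter_participants(ev2[0, ]), "empty cohort")
})
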