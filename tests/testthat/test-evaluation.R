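# accuracy metrics, gated paired tests, reliability

test_that("percent_abs_diff is the symmetric absolute relative error", {
  expect_equal(percent_abs_diff(110, 100), 10)
  expect_equal(percent_abs_diff(100, 100), 0)
  expect_equal(percent_abs_diff(95, 100), 5)
  # scale invariance
  a <- 3.7
  expect_equal(percent_abs_diff(a * 112, a * 100), percent_abs_diff(112, 100))
  expect_error(percent_abs_diff(100, 0), class = "repmax_validation_error")
})

test_that("paired_compare gates on Shapiro-Wilk and records its choice", {
  set.seed(101)
  actual <- rnorm(30, 100, 15)
  # exact predictions: nothing to test, p = 1 by convention
  same <- paired_compare(actual, actual)
  expect_equal(same$test, "none")
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # normal null: t-test branch selected
  null <- paired_compare(actual + rnorm(30), actual)
  expect_equal(null$test, "paired t-test")
  expect_gt(null$shapiro_p, 0.05)

  # a heavy shift with small jitter is detected at p <= 0.001
  shifted <- paired_compare(actual + 5 + 0.01 * rnorm(30), actual)
  expect_lte(shifted$p_value, 0.001)
  expect_equal(shifted$stars, "***")

  # strongly non-normal differences route to the signed-rank test
  skewed <- paired_compare(actual + rexp(30)^3, actual)
  expect_equal(skewed$test, "wilcoxon signed-rank")
  expect_lte(skewed$shapiro_p, 0.05)

  expect_error(paired_compare(1:4, 2:5), class = "repmax_validation_error")
})

test_that("paired_compare holds its size under a normal null", {
  set.seed(2024)
  n_rep <- 500
  rejections <- vapply(seq_len(n_rep), function(i) {
    actual <- rnorm(30, 100, 10)
    paired_compare(actual + rnorm(30), actual)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.08)
})

test_that("group_compare is the classic independent t-test", {
  x <- c(3, 4, 5, 6, 7)
  same <- group_compare(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)
  expect_error(group_compare(c(1, 1), c(2, 2)), class = "repmax_domain_error")

  # sex-difference magnitudes seen in older trained cohorts are far from
  # significance: moments 3.45 +/- 3.15 (23 women) vs 4.13 +/- 4.25 (17 men)
  scale_to <- function(z, m, s) m + s * (z - mean(z)) / sd(z)
  set.seed(55)
  women <- scale_to(rnorm(23), 3.45, 3.15)
  men <- scale_to(rnorm(17), 4.13, 4.25)
  res <- group_compare(women, men)
  expect_gt(res$p_value, 0.05)
  expect_equal(res$stars, "")
})

test_that("group_compare holds its size under a shared null", {
  set.seed(321)
  rejections <- vapply(seq_len(1000), function(i) {
    group_compare(rnorm(23, 5, 3), rnorm(17, 5, 3))$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("test_retest_cv uses the two-point within-subject SD", {
  flat <- test_retest_cv(data.frame(trial1 = c(100, 80), trial2 = c(100, 80)))
  expect_equal(flat$mean_cv, 0)
  one <- test_retest_cv(data.frame(trial1 = 95, trial2 = 105))
  # SD(95, 105) = 10/sqrt(2) = 7.0711, mean 100
  expect_equal(one$mean_cv, 100 * (10 / sqrt(2)) / 100, tolerance = 1e-12)
  expect_equal(round(one$mean_cv, 3), 7.071)
  expect_error(test_retest_cv(data.frame(trial1 = -1, trial2 = 2)),
               class = "repmax_validation_error")
})

test_that("test_retest_reps summarises absolute rep differences", {
  res <- test_retest_reps(data.frame(trial1 = c(7, 6, 8), trial2 = c(8, 6, 6)))
  expect_equal(res$mean_abs_diff, 1)
  expect_equal(res$abs_diff[[1]], c(1, 0, 2))
  zero <- test_retest_reps(data.frame(trial1 = c(8, 8), trial2 = c(8, 8)))
  expect_equal(zero$mean_abs_diff, 0)
  expect_equal(zero$sd_abs_diff, 0)
  expect_error(test_retest_reps(data.frame(trial1 = -1, trial2 = 2)),
               class = "repmax_validation_error")
})

test_that("summarize_accuracy is exact on an error-free cohort", {
  cohort <- generate_cohort(noiseless_config(seed = 17))
  fits <- fit_all_exercises(cohort, mode = "per_exercise")
  acc <- summarize_accuracy(cohort, models = fits)
  expect_equal(nrow(acc), 7 * 5)
  expect_true(all(acc$diff_mean < 1e-10))
  expect_true(all(acc$diff_sd < 1e-10))
  expect_true(all(acc$test == "none"))
  expect_true(all(acc$p_value == 1))
})

test_that("a constant +10% bias is reported as exactly 10% and significant", {
  set.seed(77)
  n <- 30
  recs <- tibble::tibble(
    participant_id = sprintf("B%02d", 1:n), sex = "female", exercise = "leg_press",
    one_rm = rnorm(n, 100, 15), isom = NA_real_,
    rtf = lapply(rnorm(n, 100, 15), function(w) {
      tibble::tibble(zone = "r8", reps = 8L, load = w)
    })
  )
  # a model whose p(8) is exactly 1.1 relative to the observation's load:
  # force load = 1RM so that prediction = 1.1 * 1RM
  recs$rtf <- lapply(recs$one_rm, function(w) tibble::tibble(zone = "r8", reps = 8L, load = w))
  biased <- cubic_model(c(1.1, 0, 0, 0), kappa = 1.1)
  acc <- summarize_accuracy(recs, predictors = "r8", models = biased)
  expect_equal(acc$diff_mean, 10, tolerance = 1e-10)
  expect_equal(acc$diff_sd, 0, tolerance = 1e-10)
  expect_lte(acc$p_value, 0.001)
  expect_equal(acc$stars, "***")
})

test_that("predictors with missing inputs report reduced n, not zeros", {
  cohort <- generate_cohort(cohort_config(n = 12, seed = 19))
  cohort$isom <- NA_real_
  acc <- summarize_accuracy(cohort, predictors = c("r8", "isom", "isom_r8"))
  isom_rows <- acc[acc$predictor %in% c("isom", "isom_r8"), ]
  expect_true(all(isom_rows$n == 0))
  expect_true(all(is.na(isom_rows$diff_mean)))
  expect_true(all(acc$n[acc$predictor == "r8"] > 0))
})

test_that("literature predictors run off the 5-8 zone observation", {
  cohort <- generate_cohort(cohort_config(n = 20, missing_rate = 0, seed = 23))
  acc <- summarize_accuracy(cohort, predictors = c("klw", "epley", "brzycki"))
  expect_equal(nrow(acc), 7 * 3)
  expect_true(all(acc$n > 0))
  expect_true(all(is.finite(acc$diff_mean)))
  # spot-check one cell against a manual computation
  lp <- cohort[cohort$exercise == "leg_press", ]
  obs <- purrr::map_dfr(lp$rtf, ~ .x[.x$zone == "r8", c("reps", "load")])
  manual <- mean(percent_abs_diff(predict_literature(obs$load, obs$reps, "klw"), lp$one_rm))
  expect_equal(acc$diff_mean[acc$exercise == "leg_press" & acc$predictor == "klw"], manual)
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(significance_stars(c(0.0005, 0.005, 0.03, 0.2, NA)),
               c("***", "**", "*", "", NA))
})
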