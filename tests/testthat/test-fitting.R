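# least-squares calibration of the cubic curve and the isometric coefficient

test_that("noiseless data generated from a known cubic is recovered exactly", {
  for (ex in c("pooled", "lat_pulls", "trunk_extension", "leg_flexion")) {
    truth <- preset_model(ex)
    records <- make_noiseless_records(truth, n = 30)
    fit <- fit_cubic(records, include_anchor = FALSE)
    expect_lt(max(abs(fit$coefficients - truth$coefficients)), 1e-8)
    expect_equal(fit$kappa, truth$kappa, tolerance = 1e-12)
  }
})

test_that("fit matches an independent normal-equations oracle", {
  # minimal 4-point instance: the oracle solves the 4x4 normal equations
  # directly; the implementation goes through QR
  truth <- preset_model("pooled")
  records <- make_noiseless_records(truth, n = 1, reps = c(2, 7, 11, 14), w1 = 90)
  fit <- fit_cubic(records, include_anchor = FALSE)
  obs <- tidyr::unnest(records[, c("one_rm", "rtf")], "rtf")
  X <- cbind(obs$load, obs$load * obs$reps, obs$load * obs$reps^2, obs$load * obs$reps^3)
  oracle <- solve(crossprod(X), crossprod(X, obs$one_rm))
  expect_equal(unname(fit$coefficients), as.numeric(oracle), tolerance = 1e-9)

  # and on an overdetermined noisy instance
  set.seed(71)
  noisy <- make_noiseless_records(truth, n = 40, reps = c(1, 6, 10, 15))
  noisy$rtf <- lapply(noisy$rtf, function(r) {
    r$load <- r$load * (1 + 0.02 * rnorm(nrow(r)))
    r
  })
  fit2 <- fit_cubic(noisy, include_anchor = FALSE)
  obs2 <- tidyr::unnest(noisy[, c("one_rm", "rtf")], "rtf")
  X2 <- cbind(obs2$load, obs2$load * obs2$reps, obs2$load * obs2$reps^2, obs2$load * obs2$reps^3)
  oracle2 <- solve(crossprod(X2), crossprod(X2, obs2$one_rm))
  expect_equal(unname(fit2$coefficients), as.numeric(oracle2), tolerance = 1e-7)
})

test_that("rank-deficient designs raise a singular-fit error", {
  truth <- preset_model("pooled")
  flat <- make_noiseless_records(truth, n = 10, reps = c(8, 8, 8, 8))
  expect_error(fit_cubic(flat, include_anchor = FALSE), class = "repmax_domain_error")
  # the anchor contributes reps = 1, still only 2 distinct values
  expect_error(fit_cubic(flat, include_anchor = TRUE), class = "repmax_domain_error")
  expect_error(fit_cubic(flat[0, ]), class = "repmax_validation_error")
})

test_that("2% load noise still recovers the curve to within 1% on 5-16", {
  set.seed(42)
  truth <- preset_model("pooled")
  records <- make_noiseless_records(truth, n = 200, reps = c(1, 6, 10, 15),
                                    w1 = runif(200, 40, 160))
  records$rtf <- lapply(records$rtf, function(r) {
    r$load <- r$load * (1 + 0.02 * rnorm(nrow(r)))
    r
  })
  fit <- fit_cubic(records, include_anchor = FALSE)
  grid <- 5:16
  p_hat <- rep_percentage(fit, grid)
  p_true <- rep_percentage(truth, grid)
  expect_lt(max(abs(p_hat / p_true - 1)), 0.01)
})

test_that("fitted coefficients minimise the squared objective", {
  set.seed(9)
  truth <- preset_model("pooled")
  records <- make_noiseless_records(truth, n = 25)
  records$rtf <- lapply(records$rtf, function(r) {
    r$load <- r$load * (1 + 0.03 * rnorm(nrow(r)))
    r
  })
  fit <- fit_cubic(records, include_anchor = FALSE)
  rss_hat <- cubic_rss(records, unname(fit$coefficients))
  scale <- pmax(abs(fit$coefficients), 1e-5)
  worse <- replicate(1000, {
    perturbed <- fit$coefficients + rnorm(4) * scale * 1e-2
    cubic_rss(records, unname(perturbed))
  })
  expect_true(all(rss_hat <= worse + 1e-12))
})

test_that("record order does not affect the fit", {
  set.seed(13)
  records <- make_noiseless_records(preset_model("lat_pulls"), n = 20)
  records$rtf <- lapply(records$rtf, function(r) {
    r$load <- r$load * (1 + 0.05 * rnorm(nrow(r)))
    r
  })
  f1 <- fit_cubic(records)
  f2 <- fit_cubic(records[sample(nrow(records)), ])
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-12)
})

test_that("the isometric coefficient is the mean of 1RM/ISOM ratios", {
  recs <- tibble::tibble(
    participant_id = c("a", "b"), sex = "female", exercise = "leg_press",
    one_rm = c(100, 102), isom = c(100, 100), rtf = list(tibble::tibble())
  )
  expect_equal(fit_isometric_coefficient(recs), 1.01)
  recs$isom <- recs$one_rm
  expect_equal(fit_isometric_coefficient(recs), 1)
  recs$isom <- NA_real_
  expect_error(fit_isometric_coefficient(recs), class = "repmax_validation_error")

  # law of large numbers around a ratio of 1.0003
  set.seed(123)
  n <- 1e4
  big <- tibble::tibble(
    participant_id = as.character(seq_len(n)), sex = "female", exercise = "leg_press",
    one_rm = 100, isom = 100 / (1.0003 + 0.05 * rnorm(n)),
    rtf = replicate(n, tibble::tibble(), simplify = FALSE)
  )
  expect_equal(fit_isometric_coefficient(big), 1.0003, tolerance = 2e-3)
  # brute-force equality on any instance
  expect_equal(fit_isometric_coefficient(big), mean(big$one_rm / big$isom))
})

test_that("pooled_transfer assigns the leg-press curve to every exercise", {
  truth <- preset_model("pooled")
  lp <- make_noiseless_records(truth, n = 15)
  lp$exercise <- "leg_press"
  fits <- fit_all_exercises(lp, mode = "pooled_transfer")
  expect_equal(fits$exercise, "leg_press")
  cohort <- generate_cohort(noiseless_config(seed = 11))
  fits_all <- fit_all_exercises(cohort, mode = "pooled_transfer")
  expect_true(all(fits_all$fitted))
  co <- t(vapply(fits_all$model, function(m) m$coefficients, numeric(4)))
  expect_true(all(apply(co, 2, function(x) max(abs(x - x[1]))) < 1e-12))
  # kappa remains exercise-specific
  kappas <- vapply(fits_all$model, function(m) m$kappa, numeric(1))
  expect_gt(max(kappas) - min(kappas), 0)
})

test_that("per-exercise fits beat the transferred curve when curves differ", {
  # distinct true curves per exercise; held-out half scored with both modes
  cfg <- cohort_config(n = 80, sigma_load = 0.01, sigma_kappa = 0.02,
                       sigma_curve = 0, missing_rate = 0, seed = 21)
  cohort <- generate_cohort(cfg)
  train <- cohort[cohort$participant_id %in% sprintf("P%03d", 1:40), ]
  test <- cohort[!cohort$participant_id %in% sprintf("P%03d", 1:40), ]
  err <- function(fits) {
    acc <- summarize_accuracy(test, predictors = c("r8", "r10", "r15"), models = fits)
    mean(acc$diff_mean)
  }
  per <- err(fit_all_exercises(train, mode = "per_exercise"))
  pooled <- err(fit_all_exercises(train, mode = "pooled_transfer"))
  expect_lte(per, pooled)
})

test_that("exercises with insufficient data are flagged, not fatal", {
  good <- generate_cohort(noiseless_config(seed = 31))
  bad <- tibble::tibble(
    participant_id = c("X1", "X2"), sex = "male", exercise = "leg_flexion",
    one_rm = c(60, 70), isom = c(60, 70),
    rtf = list(tibble::tibble(zone = "r8", reps = 8L, load = 50),
               tibble::tibble(zone = "r8", reps = 8L, load = 58))
  )
  mixed <- dplyr::bind_rows(good[good$exercise == "leg_press", ], bad)
  fits <- fit_all_exercises(mixed, mode = "per_exercise")
  expect_true(fits$fitted[fits$exercise == "leg_press"])
  expect_false(fits$fitted[fits$exercise == "leg_flexion"])
  expect_match(fits$note[fits$exercise == "leg_flexion"], "[Ss]ingular")
})
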