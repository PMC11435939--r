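# accuracy and reliability metrics

#' Absolute percent difference between predicted and actual 1RM
#'
#' @param predicted Predicted 1RM, kg.
#' @param actual Actual (measured) 1RM, kg (> 0).
#' @return `100 * |predicted - actual| / actual`, in percent.
#' @export
#' @examples
#' percent_abs_diff(110, 100)
percent_abs_diff <- function(predicted, actual) {
  check_positive(actual, "actual")
  if (!is.numeric(predicted) || any(!is.finite(predicted))) {
    abort_validation("`predicted` must be finite numbers.")
  }
  100 * abs(predicted - actual) / actual
}

#' Significance stars
#'
#' `***`, `**`, `*` at p <= 0.001, 0.01, 0.05; empty otherwise.
#'
#' @param p P-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Normality-gated paired comparison of predicted vs actual values
#'
#' Tests whether predictions differ systematically from actual 1RM values,
#' pairing by participant: the paired differences are screened with a
#' Shapiro–Wilk test; when its p-value exceeds 0.05 a paired t-test is used,
#' otherwise the Wilcoxon signed-rank test. The selected test is recorded in
#' the result for auditability.
#'
#' Conventions: differences that are all zero (below `zero_tol`, a numerical
#' zero well under the 0.1 kg resolution of the measurements) return the
#' `"none"` outcome with p = 1 — nothing to test; zero differences are
#' dropped before the Wilcoxon test
#' and an exact p-value is used below `exact_cutoff` non-zero pairs, the
#' continuity-corrected normal approximation above. Constant non-zero
#' differences (Shapiro–Wilk undefined) fall back to the Wilcoxon branch.
#'
#' @param predicted,actual Paired numeric vectors (>= 5 pairs), kg.
#' @param alpha Significance level for the `significant` flag (default 0.05,
#'   two-tailed).
#' @param exact_cutoff Number of non-zero pairs below which the exact Wilcoxon
#'   distribution is used (default 25).
#' @param zero_tol Absolute differences below this (kg) count as zero
#'   (default 1e-8).
#' @return One-row tibble: `n`, `test`, `statistic`, `p_value`, `shapiro_p`,
#'   `significant`, `stars`.
#' @export
#' @examples
#' set.seed(1)
#' a <- rnorm(30, 100, 10)
#' paired_compare(a * 1.05, a)
paired_compare <- function(predicted, actual, alpha = 0.05, exact_cutoff = 25,
                           zero_tol = 1e-8) {
  if (!is.numeric(predicted) || !is.numeric(actual) || length(predicted) != length(actual)) {
    abort_validation("`predicted` and `actual` must be numeric vectors of equal length.")
  }
  n <- length(predicted)
  if (n < 5) abort_validation("Paired comparison needs at least 5 pairs.")
  d <- predicted - actual

  result <- function(test, statistic, p, shapiro_p) {
    tibble::tibble(
      n = n, test = test, statistic = statistic, p_value = p,
      shapiro_p = shapiro_p,
      significant = !is.na(p) && p <= alpha,
      stars = significance_stars(p)
    )
  }

  if (all(abs(d) <= zero_tol)) {
    return(result("none", NA_real_, 1, NA_real_))
  }
  d_nz_all <- d[abs(d) > zero_tol]
  shapiro_p <- if (stats::sd(d) > 0) stats::shapiro.test(d)$p.value else NA_real_
  if (!is.na(shapiro_p) && shapiro_p > 0.05) {
    tt <- stats::t.test(predicted, actual, paired = TRUE)
    return(result("paired t-test", unname(tt$statistic), tt$p.value, shapiro_p))
  }
  d_nz <- d_nz_all
  exact <- length(d_nz) < exact_cutoff
  wt <- suppressWarnings(stats::wilcox.test(d_nz, mu = 0, exact = exact, correct = TRUE))
  result("wilcoxon signed-rank", unname(wt$statistic), wt$p.value, shapiro_p)
}

#' Independent two-group comparison
#'
#' Classic independent t-test (two-tailed) between two groups of
#' per-participant values — e.g. percent differences of women vs men.
#'
#' @param values_a,values_b Numeric vectors (each n >= 2).
#' @param var_equal Pooled-variance (classic) t-test if `TRUE` (default);
#'   Welch if `FALSE`.
#' @return One-row tibble: `n_a`, `n_b`, `statistic`, `df`, `p_value`,
#'   `stars`.
#' @export
group_compare <- function(values_a, values_b, var_equal = TRUE) {
  if (!is.numeric(values_a) || !is.numeric(values_b) ||
      length(values_a) < 2 || length(values_b) < 2) {
    abort_validation("Both groups must be numeric with at least 2 values.")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    abort_domain("Degenerate variance: both groups are constant; the t-test is undefined.")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  tibble::tibble(
    n_a = length(values_a), n_b = length(values_b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, stars = significance_stars(tt$p.value)
  )
}

# ---- accuracy reports -------------------------------------------------------

resolve_models <- function(models, exercises) {
  get_one <- function(ex) {
    if (is.null(models)) return(preset_model(ex))
    if (is_cubic_model(models)) return(models)
    if (is.data.frame(models)) { # fit_all_exercises() output
      row <- models[models$exercise == ex, , drop = FALSE]
      if (nrow(row) == 1 && isTRUE(row$fitted)) return(row$model[[1]])
      return(NULL)
    }
    if (is.list(models)) return(models[[ex]])
    abort_validation("`models` must be NULL, a cubic_model, a named list, or fit_all_exercises() output.")
  }
  stats::setNames(lapply(exercises, get_one), exercises)
}

predictor_values <- function(recs, predictor, model, variant) {
  zone_obs <- function(zone) {
    purrr::map_dfr(recs$rtf, function(rtf) {
      hit <- which(rtf$zone == zone)
      if (length(hit) == 0) {
        tibble::tibble(reps = NA_integer_, load = NA_real_)
      } else {
        tibble::tibble(reps = rtf$reps[hit[1]], load = rtf$load[hit[1]])
      }
    })
  }
  predict_zone <- function(zone) {
    obs <- zone_obs(zone)
    ok <- !is.na(obs$load)
    pred <- rep(NA_real_, nrow(recs))
    if (any(ok) && !is.null(model)) {
      pred[ok] <- predict_cubic(model, obs$load[ok], obs$reps[ok])
    }
    pred
  }
  if (predictor %in% c("r8", "r10", "r15")) {
    predict_zone(predictor)
  } else if (predictor == "isom") {
    pred <- rep(NA_real_, nrow(recs))
    if (!is.null(model) && !is.na(model$kappa)) {
      ok <- !is.na(recs$isom)
      if (any(ok)) pred[ok] <- predict_isometric(model, recs$isom[ok])
    }
    pred
  } else if (predictor == "isom_r8") {
    (predictor_values(recs, "r8", model, variant) +
       predictor_values(recs, "isom", model, variant)) / 2
  } else if (predictor %in% literature_equation_names()) {
    obs <- zone_obs("r8")
    ok <- !is.na(obs$load)
    pred <- rep(NA_real_, nrow(recs))
    if (any(ok)) {
      pred[ok] <- predict_literature(obs$load[ok], obs$reps[ok], predictor, variant)
    }
    pred
  } else {
    abort_validation(sprintf(
      "Unknown predictor '%s'. Use r8/r10/r15/isom/isom_r8 or a literature equation name.",
      predictor
    ))
  }
}

#' Summarise predictor accuracy per exercise
#'
#' For each exercise and each requested predictor, computes the mean and SD of
#' the predicted 1RM, of the actual 1RM, and of the absolute percent
#' difference, together with the normality-gated paired test of
#' [paired_compare()]. Predictors:
#'
#' * `"r8"`, `"r10"`, `"r15"` — the cubic model applied to the RTF observation
#'   of the 5–8, 9–12 or 13–16 rep zone;
#' * `"isom"` — the isometric coefficient applied to the isometric maximum;
#' * `"isom_r8"` — the mean of the `isom` and `r8` predictions;
#' * any literature equation name (see [literature_equations()]), applied to
#'   the 5–8 zone observation.
#'
#' Records lacking the inputs a predictor needs are dropped from that cell
#' (reported through the cell's `n`), never imputed as zero.
#'
#' @param records A `strength_records` tibble.
#' @param predictors Character vector of predictor labels (default the five
#'   model-based predictors).
#' @param models Model source: `NULL` for the bundled presets (the pooled
#'   curve for the leg press, exercise-specific curves elsewhere), a single
#'   [cubic_model()] used everywhere, a named list of models, or the tibble
#'   from [fit_all_exercises()].
#' @param variant Coefficient variant for literature predictors.
#' @param alpha Significance level for the paired test.
#' @return A tibble of class `rm_accuracy`: one row per exercise x predictor
#'   with columns `exercise`, `predictor`, `n`, `pred_mean`, `pred_sd`,
#'   `actual_mean`, `actual_sd`, `diff_mean`, `diff_sd`, `test`, `statistic`,
#'   `p_value`, `stars`. SDs use the n - 1 denominator.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' summarize_accuracy(cohort, predictors = c("r8", "isom_r8", "klw"))
summarize_accuracy <- function(records,
                               predictors = c("r8", "r10", "r15", "isom", "isom_r8"),
                               models = NULL,
                               variant = c("canonical", "as_printed"),
                               alpha = 0.05) {
  variant <- rlang::arg_match(variant)
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_validation("`records` must be a non-empty strength-records tibble.")
  }
  exercises <- unique(records$exercise)
  model_map <- resolve_models(models, exercises)

  out <- purrr::map_dfr(exercises, function(ex) {
    recs <- records[records$exercise == ex, , drop = FALSE]
    purrr::map_dfr(predictors, function(pr) {
      pred <- predictor_values(recs, pr, model_map[[ex]], variant)
      ok <- !is.na(pred)
      n <- sum(ok)
      if (n == 0) {
        return(tibble::tibble(
          exercise = ex, predictor = pr, n = 0L,
          pred_mean = NA_real_, pred_sd = NA_real_,
          actual_mean = NA_real_, actual_sd = NA_real_,
          diff_mean = NA_real_, diff_sd = NA_real_,
          test = NA_character_, statistic = NA_real_, p_value = NA_real_,
          stars = NA_character_
        ))
      }
      p <- pred[ok]
      a <- recs$one_rm[ok]
      pd <- percent_abs_diff(p, a)
      cmp <- if (n >= 5) {
        paired_compare(p, a, alpha = alpha)
      } else {
        tibble::tibble(test = NA_character_, statistic = NA_real_,
                       p_value = NA_real_, stars = NA_character_)
      }
      tibble::tibble(
        exercise = ex, predictor = pr, n = as.integer(n),
        pred_mean = mean(p), pred_sd = stats::sd(p),
        actual_mean = mean(a), actual_sd = stats::sd(a),
        diff_mean = mean(pd), diff_sd = stats::sd(pd),
        test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value,
        stars = cmp$stars
      )
    })
  })
  class(out) <- c("rm_accuracy", class(out))
  out
}

# ---- test-retest reliability ------------------------------------------------

#' Test–retest coefficient of variation
#'
#' Per-participant CV of a twice-measured quantity, using the two-point
#' within-subject SD: \eqn{CV_i = 100\,|x_{1i} - x_{2i}| / (\sqrt{2}\,
#' \bar{x}_i)}. Note some reliability conventions use \eqn{|x_{1i} -
#' x_{2i}|/\bar{x}_i} instead,
#' which differs by \eqn{\sqrt 2}.
#'
#' @param data Data frame with one row per participant and two trial columns
#'   (e.g. from [generate_retest()]).
#' @param trial1,trial2 Columns holding the two trials (tidy-eval; default
#'   `trial1`, `trial2`). Loads must be positive.
#' @return One-row tibble of class `rm_reliability`: `n`, `mean_cv`, `sd_cv`
#'   (cohort mean ± SD of the per-participant CVs, %) and `cv`, a list-column
#'   with the per-participant values.
#' @export
#' @examples
#' test_retest_cv(data.frame(trial1 = c(100, 95), trial2 = c(100, 105)))
test_retest_cv <- function(data, trial1 = trial1, trial2 = trial2) {
  x1 <- dplyr::pull(data, {{ trial1 }})
  x2 <- dplyr::pull(data, {{ trial2 }})
  check_positive(x1, "trial1")
  check_positive(x2, "trial2")
  cv <- 100 * (abs(x1 - x2) / sqrt(2)) / ((x1 + x2) / 2)
  out <- tibble::tibble(
    n = length(cv), mean_cv = mean(cv), sd_cv = stats::sd(cv), cv = list(cv)
  )
  class(out) <- c("rm_reliability", class(out))
  out
}

#' Test–retest repetition agreement
#'
#' Cohort mean ± SD of the per-participant absolute difference in repetitions
#' between two RTF trials at the same load.
#'
#' @param data Data frame with one row per participant and two trial columns
#'   of whole repetition counts.
#' @inheritParams test_retest_cv
#' @return One-row tibble: `n`, `mean_abs_diff`, `sd_abs_diff`, `abs_diff`
#'   (list-column of per-participant values).
#' @export
#' @examples
#' test_retest_reps(data.frame(trial1 = c(7, 6, 8), trial2 = c(8, 6, 6)))
test_retest_reps <- function(data, trial1 = trial1, trial2 = trial2) {
  r1 <- dplyr::pull(data, {{ trial1 }})
  r2 <- dplyr::pull(data, {{ trial2 }})
  if (!rlang::is_integerish(r1) || !rlang::is_integerish(r2) ||
      any(r1 < 0) || any(r2 < 0)) {
    abort_validation("Trials must be non-negative whole repetition counts.")
  }
  d <- abs(r1 - r2)
  tibble::tibble(
    n = length(d), mean_abs_diff = mean(d), sd_abs_diff = stats::sd(d),
    abs_diff = list(d)
  )
}
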