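# seeded synthetic-cohort simulator
#
# Emulates the measurement structure of the calibration study: ~40 trained
# older adults, 7 machine exercises, per participant x exercise an actual 1RM,
# an isometric maximum, and one RTF observation per repetition zone
# (5-8, 9-12, 13-16). All randomness flows through one seed; standard-normal /
# uniform draws are taken unconditionally and scaled afterwards, so runs that
# differ only in a noise scale share common random numbers.

default_anchors <- function() {
  tibble::tribble(
    ~exercise,         ~mean_1rm, ~sd_1rm,
    "leg_press",           129.5,    41.1,
    "lat_pulls",            80.9,    30.3,
    "triceps_dips",        116.9,    42.8,
    "trunk_extension",      71.2,    19.2,
    "trunk_flexion",        48.6,    17.7,
    "leg_extension",        81.8,    18.2,
    "leg_flexion",          62.8,    22.0
  )
}

default_retest_cv <- function() {
  c(leg_press = 3.3, lat_pulls = 3.3, triceps_dips = 5.4, trunk_extension = 3.6,
    trunk_flexion = 4.4, leg_extension = 3.9, leg_flexion = 4.6)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the structure and magnitudes of the calibration cohort:
#' 40 participants (17 men / 23 women), seven machine exercises with actual
#' 1RM means and SDs matching the cohort's per-exercise values (e.g. leg
#' press 129.5 ± 41.1 kg), true rep-percentage curves equal to the bundled
#' presets, isometric ratio scatter, 2% multiplicative load noise, ±1-rep
#' performance jitter, per-participant rep-tolerance heterogeneity (the
#' mechanism by which prediction error grows with the repetition zone), and
#' a per-exercise missingness rate that lands complete n around 32–36.
#'
#' @param n Number of participants.
#' @param prop_male Proportion of men (men are listed first).
#' @param exercises Exercises to simulate.
#' @param anchors Tibble `exercise`, `mean_1rm`, `sd_1rm` (kg) giving the
#'   target marginal distribution of actual 1RM per exercise.
#' @param models Named list of true [cubic_model()] curves per exercise;
#'   `NULL` uses the bundled presets (pooled curve for the leg press).
#' @param sigma_load Multiplicative SD of load realisation noise (default
#'   0.02, i.e. 2%).
#' @param sigma_kappa SD of the per-record 1RM/ISOM ratio around the true
#'   isometric coefficient (default 0.08).
#' @param sigma_curve Per-rep SD of the participant-level deviation from the
#'   population rep-percentage curve (default 0.005/rep): individual curves
#'   are `p(r) * exp(gamma * (r - 1))` with `gamma ~ N(0, sigma_curve)`.
#' @param sigma_participant Log-scale SD of the strength factor shared by a
#'   participant across exercises (default 0.15).
#' @param male_ratio Median male/female strength ratio (default 1.7).
#' @param target_reps Named target repetitions per zone (default r8 = 8,
#'   r10 = 10, r15 = 15).
#' @param rep_jitter_probs Probabilities of a -1/0/+1 rep deviation from the
#'   target (default 0.25/0.5/0.25); must sum to 1.
#' @param rep_sampling `"fixed"` targets with jitter (default) or `"uniform"`
#'   draws over the full zone.
#' @param missing_rate Probability that a participant misses an exercise
#'   entirely (default 0.12).
#' @param round_loads Round RTF loads to 1 kg plate increments (default
#'   `FALSE`).
#' @param retest_cv Named per-exercise within-subject CV (%) for
#'   [generate_retest()] (defaults 3.3–5.4).
#' @param retest_n Participants in the retest subsample (default 10).
#' @param seed Integer seed; fully determines the output.
#' @return A validated `cohort_config` list.
#' @export
#' @examples
#' cohort_config(n = 10, seed = 7)
cohort_config <- function(n = 40, prop_male = 17 / 40, exercises = rm_exercises(),
                          anchors = default_anchors(), models = NULL,
                          sigma_load = 0.02, sigma_kappa = 0.08,
                          sigma_curve = 0.005, sigma_participant = 0.15,
                          male_ratio = 1.7,
                          target_reps = c(r8 = 8, r10 = 10, r15 = 15),
                          rep_jitter_probs = c(0.25, 0.5, 0.25),
                          rep_sampling = c("fixed", "uniform"),
                          missing_rate = 0.12, round_loads = FALSE,
                          retest_cv = default_retest_cv(), retest_n = 10,
                          seed = 1L) {
  rep_sampling <- rlang::arg_match(rep_sampling)
  if (!rlang::is_integerish(n) || n < 1) abort_validation("`n` must be a positive integer.")
  if (prop_male < 0 || prop_male > 1) abort_validation("`prop_male` must be in [0, 1].")
  if (!all(exercises %in% anchors$exercise)) {
    abort_validation("Every exercise needs an anchor row (mean_1rm, sd_1rm).")
  }
  for (nm in c("sigma_load", "sigma_kappa", "sigma_curve", "sigma_participant")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      abort_validation(sprintf("`%s` must be a single non-negative number.", nm))
    }
  }
  check_positive(anchors$mean_1rm, "anchors$mean_1rm")
  check_positive(anchors$sd_1rm, "anchors$sd_1rm")
  check_positive(male_ratio, "male_ratio")
  if (length(rep_jitter_probs) != 3 || any(rep_jitter_probs < 0) ||
      abs(sum(rep_jitter_probs) - 1) > 1e-8) {
    abort_validation("`rep_jitter_probs` must be three non-negative probabilities summing to 1.")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort_validation("`missing_rate` must be in [0, 1).")
  if (!all(c("r8", "r10", "r15") %in% names(target_reps))) {
    abort_validation("`target_reps` must name r8, r10 and r15.")
  }
  if (!rlang::is_integerish(retest_n) || retest_n < 2) {
    abort_validation("`retest_n` must be an integer >= 2.")
  }
  if (!rlang::is_integerish(seed)) abort_validation("`seed` must be an integer.")
  if (!is.null(models)) {
    if (!all(exercises %in% names(models)) ||
        !all(vapply(models[exercises], is_cubic_model, logical(1)))) {
      abort_validation("`models` must be a named list of cubic_model objects covering every exercise.")
    }
  }
  structure(
    list(
      n = as.integer(n), prop_male = prop_male, exercises = exercises,
      anchors = anchors, models = models,
      sigma_load = sigma_load, sigma_kappa = sigma_kappa,
      sigma_curve = sigma_curve, sigma_participant = sigma_participant,
      male_ratio = male_ratio, target_reps = target_reps,
      rep_jitter_probs = rep_jitter_probs, rep_sampling = rep_sampling,
      missing_rate = missing_rate, round_loads = round_loads,
      retest_cv = retest_cv, retest_n = as.integer(retest_n),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

truth_model <- function(config, exercise) {
  if (is.null(config$models)) preset_model(exercise) else config$models[[exercise]]
}

# log-normal strength model: log w1 = mu_e + beta*male + u_i + eps_ie, with
# mu_e chosen so the sex-mixture mean equals the anchor mean and the residual
# variance filled up to match the anchor CV
strength_log_params <- function(config, exercise) {
  row <- config$anchors[config$anchors$exercise == exercise, , drop = FALSE]
  beta <- log(config$male_ratio)
  p <- config$prop_male
  v_target <- log(1 + (row$sd_1rm / row$mean_1rm)^2)
  v_sex <- p * (1 - p) * beta^2
  v_resid <- max(0.002, v_target - v_sex - config$sigma_participant^2)
  v_ind <- config$sigma_participant^2 + v_resid
  mu <- log(row$mean_1rm) - v_ind / 2 - log(p * exp(beta) + (1 - p))
  list(mu = mu, beta = beta, sigma_resid = sqrt(v_resid))
}

zone_bounds <- function(zone) {
  switch(zone, r8 = c(5L, 8L), r10 = c(9L, 12L), r15 = c(13L, 16L))
}

draw_reps <- function(config, zone, u) {
  if (config$rep_sampling == "uniform") {
    b <- zone_bounds(zone)
    as.integer(pmin(b[2], b[1] + floor(u * (b[2] - b[1] + 1))))
  } else {
    p <- cumsum(config$rep_jitter_probs)
    jitter <- ifelse(u < p[1], -1L, ifelse(u < p[2], 0L, 1L))
    as.integer(config$target_reps[[zone]]) + jitter
  }
}

#' Generate a synthetic strength-testing cohort
#'
#' Draws a cohort under the generative model of [cohort_config()] and returns
#' it as a `strength_records` tibble. The hidden ground truth (true 1RM,
#' isometric ratio and individual curve deviation per participant x exercise)
#' is attached as an attribute, retrievable with [cohort_truth()], so that
#' recovery of known quantities can be tested end to end.
#'
#' @param config A [cohort_config()]. Its `seed` fully determines the output.
#' @return A `strength_records` tibble with attributes `truth` and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 10, seed = 3))
#' cohort_truth(cohort)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n
    n_male <- round(n * config$prop_male)
    sex <- c(rep("male", n_male), rep("female", n - n_male))
    ids <- sprintf("P%03d", seq_len(n))
    u <- stats::rnorm(n, 0, config$sigma_participant)

    records <- list()
    truth <- list()
    for (ex in config$exercises) {
      pars <- strength_log_params(config, ex)
      model <- truth_model(config, ex)
      eps <- stats::rnorm(n)
      z_kappa <- stats::rnorm(n)
      gamma <- stats::rnorm(n)
      u_reps <- stats::runif(n * 3)
      z_load <- stats::rnorm(n * 3)
      u_miss <- stats::runif(n)

      w1 <- exp(pars$mu + pars$beta * (sex == "male") + u + pars$sigma_resid * eps)
      ratio <- pmax(0.5, model$kappa + config$sigma_kappa * z_kappa)
      isom <- w1 / ratio
      g <- config$sigma_curve * gamma

      rtf <- purrr::map(seq_len(n), function(i) {
        zones <- c("r8", "r10", "r15")
        reps <- vapply(seq_along(zones), function(k) {
          draw_reps(config, zones[k], u_reps[(k - 1) * n + i])
        }, integer(1))
        p_ind <- eval_poly(model$coefficients, reps) * exp(g[i] * (reps - 1))
        noise <- pmax(0.2, 1 + config$sigma_load * z_load[(seq_along(zones) - 1) * n + i])
        load <- w1[i] / p_ind * noise
        if (config$round_loads) load <- pmax(1, round(load))
        tibble::tibble(zone = zones, reps = reps, load = load)
      })

      keep <- u_miss >= config$missing_rate
      records[[ex]] <- tibble::tibble(
        participant_id = ids, sex = sex, exercise = ex,
        one_rm = w1, isom = isom, rtf = rtf
      )[keep, , drop = FALSE]
      truth[[ex]] <- tibble::tibble(
        participant_id = ids, exercise = ex, true_1rm = w1,
        isom_ratio = ratio, gamma = g, observed = keep
      )
    }
    out <- new_strength_records(dplyr::bind_rows(records))
    attr(out, "truth") <- dplyr::bind_rows(truth)
    attr(out, "config") <- config
    out
  })
}

#' Ground truth of a simulated cohort
#'
#' @param records Output of [generate_cohort()].
#' @return Tibble `participant_id`, `exercise`, `true_1rm`, `isom_ratio`,
#'   `gamma`, `observed`.
#' @export
cohort_truth <- function(records) {
  truth <- attr(records, "truth")
  if (is.null(truth)) abort_validation("No truth table attached; was this generated by generate_cohort()?")
  truth
}

#' Generate paired test–retest trials
#'
#' Simulates the reliability subsample: two trials per participant sharing the
#' participant's true value, with independent within-subject noise.
#'
#' For `measurement = "one_rm"` the configured per-exercise CV (%) sets the
#' trial noise; the scale is calibrated so that the *expected cohort mean* of
#' the two-point CV computed by [test_retest_cv()] equals the configured
#' value (the half-normal mean of |x1 - x2|/sqrt(2) is `sigma * sqrt(2/pi)`,
#' so the generator uses `sigma = cv * sqrt(pi/2)`).
#'
#' For `measurement = "rtf8"` both trials draw the repetition count at the
#' fixed 5–8-zone load independently with the configured rep jitter.
#'
#' @param config A [cohort_config()]; `retest_n` and `retest_cv` apply.
#' @param measurement `"one_rm"` or `"rtf8"`.
#' @param exercise Exercise whose CV / target reps to use.
#' @return Tibble `participant`, `trial1`, `trial2`.
#' @export
#' @examples
#' generate_retest(cohort_config(seed = 2), "one_rm", "leg_press")
generate_retest <- function(config = cohort_config(),
                            measurement = c("one_rm", "rtf8"),
                            exercise = "leg_press") {
  stopifnot(inherits(config, "cohort_config"))
  measurement <- rlang::arg_match(measurement)
  withr::with_seed(config$seed, {
    n <- config$retest_n
    ids <- sprintf("R%03d", seq_len(n))
    if (measurement == "one_rm") {
      cv <- config$retest_cv[[exercise]]
      if (is.null(cv)) abort_validation(sprintf("No retest CV configured for '%s'.", exercise))
      pars <- strength_log_params(config, exercise)
      n_male <- round(n * config$prop_male)
      male <- seq_len(n) <= n_male
      truth <- exp(pars$mu + pars$beta * male +
                     stats::rnorm(n, 0, config$sigma_participant) +
                     pars$sigma_resid * stats::rnorm(n))
      sigma <- cv / 100 * sqrt(pi / 2)
      z <- matrix(stats::rnorm(2 * n), ncol = 2)
      tibble::tibble(
        participant = ids,
        trial1 = truth * pmax(0.2, 1 + sigma * z[, 1]),
        trial2 = truth * pmax(0.2, 1 + sigma * z[, 2])
      )
    } else {
      u <- matrix(stats::runif(2 * n), ncol = 2)
      tibble::tibble(
        participant = ids,
        trial1 = draw_reps(config, "r8", u[, 1]),
        trial2 = draw_reps(config, "r8", u[, 2])
      )
    }
  })
}
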