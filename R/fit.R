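# least-squares calibration of the cubic rep-percentage curve
#
# model: w1 ~ p(r) * w  with p cubic in r, i.e. linear in (c0..c3) with
# regressors (w, w*r, w*r^2, w*r^3) and response w1; solved by QR.

assemble_fit_pairs <- function(records, include_anchor = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_validation("`records` must be a non-empty strength-records tibble.")
  }
  obs <- purrr::pmap_dfr(
    records[, c("participant_id", "one_rm", "rtf")],
    function(participant_id, one_rm, rtf) {
      out <- tibble::tibble(
        participant_id = participant_id,
        one_rm = one_rm,
        reps = if (nrow(rtf) > 0) as.numeric(rtf$reps) else numeric(),
        load = if (nrow(rtf) > 0) rtf$load else numeric()
      )
      if (include_anchor) {
        # the 1RM itself is one more (load, reps) pair: w1 lifted once
        out <- dplyr::bind_rows(
          tibble::tibble(participant_id = participant_id, one_rm = one_rm,
                         reps = 1, load = one_rm),
          out
        )
      }
      out
    }
  )
  if (nrow(obs) == 0) abort_validation("No RTF observations to fit.")
  check_positive(obs$load, "rtf load")
  check_positive(obs$one_rm, "one_rm")
  obs
}

#' Fit the cubic rep-percentage curve by least squares
#'
#' Estimates `c(c0, c1, c2, c3)` of the curve \eqn{p(x)} minimising
#' \eqn{\sum_i (w_1 - p(r_i)\,w_i)^2} over all pooled RTF observations
#' \eqn{(r_i, w_i)} with per-record target \eqn{w_1} (the actual 1RM). The
#' problem is linear in the coefficients and solved by a QR decomposition —
#' no iterative optimiser. With `include_anchor = TRUE` each record also
#' contributes the pair (reps = 1, load = \eqn{w_1}), encoding that the 1RM
#' load was lifted exactly once.
#'
#' Residuals are in absolute kg, so heavier participants weigh more in the
#' fit; `normalize_loss = TRUE` divides each residual by the record's 1RM for
#' a sensitivity analysis on relative error.
#'
#' @param records A `strength_records` tibble (see [as_strength_records()] or
#'   [generate_cohort()]).
#' @param include_anchor Add the (1, w1) pseudo-observation per record
#'   (default `TRUE`).
#' @param normalize_loss Weight residuals by 1/w1 (default `FALSE`).
#' @param exercise Label stored on the returned model; defaults to the single
#'   exercise present in `records` (or `"pooled"` if several).
#' @return A [cubic_model()] whose `kappa` is fitted from the records with an
#'   isometric maximum (or `NA` if none have one), with fit diagnostics in
#'   `$fit` (see [glance.cubic_model()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' fit_cubic(dplyr::filter(cohort, exercise == "leg_press"))
fit_cubic <- function(records, include_anchor = TRUE, normalize_loss = FALSE,
                      exercise = NULL) {
  obs <- assemble_fit_pairs(records, include_anchor)
  if (dplyr::n_distinct(obs$reps) < 4) {
    abort_domain(sprintf(
      "Singular fit: only %d distinct repetition value(s); the cubic needs at least 4.",
      dplyr::n_distinct(obs$reps)
    ))
  }
  X <- cbind(obs$load, obs$load * obs$reps, obs$load * obs$reps^2, obs$load * obs$reps^3)
  y <- obs$one_rm
  if (normalize_loss) {
    X <- X / y
    y <- rep(1, length(y))
  }
  qr_x <- qr(X)
  if (qr_x$rank < 4) {
    abort_domain("Singular fit: the design matrix is rank-deficient.")
  }
  coefs <- qr.coef(qr_x, y)
  resid <- y - X %*% coefs
  d <- svd(X, nu = 0, nv = 0)$d
  exercise <- exercise %||% {
    ex <- unique(records$exercise)
    if (length(ex) == 1) ex else "pooled"
  }
  kappa <- if (any(!is.na(records$isom))) fit_isometric_coefficient(records) else NA_real_
  cubic_model(
    coefficients = as.numeric(coefs),
    kappa = kappa,
    exercise = exercise,
    fit = list(
      n_records = nrow(records),
      n_obs = nrow(obs),
      rss = sum(resid^2),
      sigma = sqrt(sum(resid^2) / max(1, nrow(obs) - 4)),
      rank = qr_x$rank,
      condition_number = d[1] / d[4],
      include_anchor = include_anchor,
      normalize_loss = normalize_loss
    )
  )
}

#' Fit the isometric coefficient
#'
#' The isometric coefficient \eqn{\kappa} is the arithmetic mean of the
#' per-record ratios 1RM / isometric maximum, over records that have an
#' isometric measurement.
#'
#' @inheritParams fit_cubic
#' @return The scalar \eqn{\kappa}.
#' @export
fit_isometric_coefficient <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_validation("`records` must be a non-empty strength-records tibble.")
  }
  with_isom <- records[!is.na(records$isom), , drop = FALSE]
  if (nrow(with_isom) == 0) {
    abort_validation("No record has an isometric measurement; cannot fit kappa.")
  }
  check_positive(with_isom$isom, "isom")
  check_positive(with_isom$one_rm, "one_rm")
  mean(with_isom$one_rm / with_isom$isom)
}

#' Fit cubic models for every exercise
#'
#' Two calibration strategies: `"per_exercise"` fits an independent curve per
#' exercise; `"pooled_transfer"` fits a single curve on the leg-press records
#' and transfers it to every other exercise. In both modes the isometric
#' coefficient is fitted per exercise.
#'
#' @inheritParams fit_cubic
#' @param mode `"per_exercise"` (default) or `"pooled_transfer"`.
#' @return A tibble with one row per exercise: `exercise`, `model`
#'   (list-column of [cubic_model()] or `NULL`), `fitted` (logical), `n_records`,
#'   and `note` (why a fit was skipped, else `NA`). Exercises with
#'   insufficient data are flagged, not fatal.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' fit_all_exercises(cohort, mode = "pooled_transfer")
fit_all_exercises <- function(records, mode = c("per_exercise", "pooled_transfer"),
                              include_anchor = TRUE, normalize_loss = FALSE) {
  mode <- rlang::arg_match(mode)
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_validation("`records` must be a non-empty strength-records tibble.")
  }
  exercises <- unique(records$exercise)

  fit_kappa_safely <- function(sub) {
    tryCatch(fit_isometric_coefficient(sub), error = function(e) NA_real_)
  }

  if (mode == "pooled_transfer") {
    base <- records[records$exercise == "leg_press", , drop = FALSE]
    if (nrow(base) == 0) {
      abort_validation("pooled_transfer mode needs leg_press records to fit the base curve.")
    }
    base_fit <- fit_cubic(base, include_anchor, normalize_loss, exercise = "pooled")
    rows <- purrr::map(exercises, function(ex) {
      sub <- records[records$exercise == ex, , drop = FALSE]
      m <- base_fit
      m$exercise <- ex
      m$kappa <- fit_kappa_safely(sub)
      tibble::tibble(exercise = ex, model = list(m), fitted = TRUE,
                     n_records = nrow(sub), note = NA_character_)
    })
  } else {
    rows <- purrr::map(exercises, function(ex) {
      sub <- records[records$exercise == ex, , drop = FALSE]
      m <- tryCatch(
        fit_cubic(sub, include_anchor, normalize_loss, exercise = ex),
        error = function(e) e
      )
      if (inherits(m, "error")) {
        tibble::tibble(exercise = ex, model = list(NULL), fitted = FALSE,
                       n_records = nrow(sub), note = conditionMessage(m))
      } else {
        tibble::tibble(exercise = ex, model = list(m), fitted = TRUE,
                       n_records = nrow(sub), note = NA_character_)
      }
    })
  }
  dplyr::bind_rows(rows)
}
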