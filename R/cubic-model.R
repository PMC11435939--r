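#' Construct a cubic rep-percentage model
#'
#' The core predictor of the package is a cubic "rep-percentage" curve
#' \deqn{p(x) = c_0 + c_1 x + c_2 x^2 + c_3 x^3}
#' such that 1RM is approximated by \eqn{p(\mathrm{reps}) \times
#' \mathrm{load}}. An optional isometric coefficient \eqn{\kappa} (the mean of
#' 1RM/isometric-maximum ratios) converts an isometric maximum into a 1RM
#' prediction via \eqn{\kappa \times \mathrm{ISOM}}.
#'
#' @param coefficients Numeric vector `c(c0, c1, c2, c3)`.
#' @param kappa Isometric coefficient (> 0), or `NA` if no isometric data are
#'   available for the model.
#' @param exercise Exercise label (free text; bundled presets use
#'   [rm_exercises()] names or `"pooled"`).
#' @param valid_reps Closed integer interval of repetitions over which the
#'   curve is considered calibrated. Predictions outside it warn; repetitions
#'   outside `[1, 20]` are rejected outright (the cubic's negative leading
#'   coefficient makes far extrapolation unsafe).
#' @param fit Optional list of fit diagnostics (attached by [fit_cubic()]).
#' @return An object of class `cubic_model`.
#' @seealso [cubic_presets()], [predict_cubic()], [fit_cubic()]
#' @export
#' @examples
#' m <- cubic_model(c(1, 0.01, 0, 0), kappa = 1)
#' predict_cubic(m, load = 100, reps = 10)
cubic_model <- function(coefficients, kappa = NA_real_, exercise = "custom",
                        valid_reps = c(1L, 16L), fit = NULL) {
  if (!is.numeric(coefficients) || length(coefficients) != 4 || any(!is.finite(coefficients))) {
    abort_validation("`coefficients` must be four finite numbers c(c0, c1, c2, c3).")
  }
  if (!rlang::is_integerish(valid_reps) || length(valid_reps) != 2 ||
      valid_reps[1] < 1 || valid_reps[2] < valid_reps[1] || valid_reps[2] > 20) {
    abort_validation("`valid_reps` must be an integer interval within [1, 20].")
  }
  if (!is.na(kappa) && (!is.numeric(kappa) || kappa <= 0)) {
    abort_validation("`kappa` must be > 0 (or NA when unavailable).")
  }
  grid <- seq(valid_reps[1], valid_reps[2])
  p <- eval_poly(coefficients, grid)
  if (any(!is.finite(p)) || any(p <= 0)) {
    abort_domain("The rep-percentage polynomial must be finite and > 0 over `valid_reps`.")
  }
  structure(
    list(
      exercise = exercise,
      coefficients = stats::setNames(as.numeric(coefficients), c("c0", "c1", "c2", "c3")),
      kappa = as.numeric(kappa),
      valid_reps = as.integer(valid_reps),
      fit = fit
    ),
    class = "cubic_model"
  )
}

eval_poly <- function(coefficients, x) {
  co <- unname(coefficients)
  co[1] + co[2] * x + co[3] * x^2 + co[4] * x^3
}

is_cubic_model <- function(x) inherits(x, "cubic_model")

#' Rep-percentage curve of a cubic model
#'
#' Evaluates the dimensionless multiplier \eqn{p(\mathrm{reps})} such that
#' predicted 1RM = `p(reps) * load`.
#'
#' @param model A [cubic_model()].
#' @param reps Whole repetition counts.
#' @return Numeric vector of multipliers.
#' @export
#' @examples
#' rep_percentage(preset_model("pooled"), 5:16)
rep_percentage <- function(model, reps) {
  stopifnot(is_cubic_model(model))
  reps <- check_reps(reps, model$valid_reps)
  p <- eval_poly(model$coefficients, reps)
  if (any(p <= 0)) {
    abort_domain("Rep-percentage p(reps) is non-positive at the supplied reps.")
  }
  p
}

# ---- bundled presets --------------------------------------------------------

presets_cache <- new.env(parent = emptyenv())

#' Bundled cubic coefficient presets
#'
#' Coefficient sets calibrated on a cohort of trained older adults with
#' osteopenia/osteoporosis: a pooled curve derived from the leg-press exercise
#' (also used for leg-press predictions) and six exercise-specific curves.
#' Each preset carries an isometric coefficient. The registry ships as a
#' plain-text YAML file (`system.file("extdata/presets.yaml", package =
#' "repmax")`).
#'
#' @return A tibble with columns `preset`, `exercise`, `c0`..`c3`, `kappa`,
#'   `min_reps`, `max_reps`.
#' @seealso [preset_model()]
#' @export
#' @examples
#' cubic_presets()
cubic_presets <- function() {
  if (is.null(presets_cache$table)) {
    path <- system.file("extdata", "presets.yaml", package = "repmax")
    presets_cache$table <- read_presets(path)
  }
  presets_cache$table
}

#' Read / write a coefficient preset registry
#'
#' The registry format is YAML: one entry per preset with fields `exercise`,
#' `coefficients` (c0..c3), `kappa` and `valid_reps`. [fit_all_exercises()]
#' output can be serialized with `write_presets()` and fed back to
#' [preset_model()] consumers or the command-line `predict` tool.
#'
#' @param path File path.
#' @return `read_presets()` returns the registry tibble (see
#'   [cubic_presets()]); `write_presets()` returns `path` invisibly.
#' @export
read_presets <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("Preset file not found: %s", path))
  raw <- yaml::read_yaml(path)
  purrr::imap_dfr(raw, function(entry, name) {
    co <- as.numeric(entry$coefficients)
    if (length(co) != 4) abort_validation(sprintf("Preset '%s' must have 4 coefficients.", name))
    vr <- as.integer(entry$valid_reps %||% c(1L, 16L))
    tibble::tibble(
      preset = name,
      exercise = entry$exercise %||% name,
      c0 = co[1], c1 = co[2], c2 = co[3], c3 = co[4],
      kappa = as.numeric(entry$kappa %||% NA_real_),
      min_reps = vr[1], max_reps = vr[2]
    )
  })
}

#' @param models Named list of [cubic_model()] objects, or the tibble returned
#'   by [fit_all_exercises()].
#' @rdname read_presets
#' @export
write_presets <- function(models, path) {
  if (is.data.frame(models)) {
    fitted <- models[models$fitted, , drop = FALSE]
    models <- stats::setNames(fitted$model, fitted$exercise)
  }
  stopifnot(all(vapply(models, is_cubic_model, logical(1))))
  out <- purrr::map(models, function(m) {
    list(
      exercise = m$exercise,
      coefficients = unname(m$coefficients),
      kappa = if (is.na(m$kappa)) NULL else m$kappa,
      valid_reps = m$valid_reps
    )
  })
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Retrieve a bundled preset as a cubic model
#'
#' @param exercise One of [rm_exercises()] or `"pooled"`. The leg press maps
#'   to the pooled curve, which was derived from leg-press data.
#' @return A [cubic_model()].
#' @export
#' @examples
#' preset_model("lat_pulls")
preset_model <- function(exercise = "pooled") {
  tab <- cubic_presets()
  key <- if (identical(exercise, "leg_press")) "pooled" else exercise
  row <- tab[tab$preset == key, , drop = FALSE]
  if (nrow(row) != 1) {
    abort_validation(sprintf(
      "No bundled preset for '%s'. Available: %s.", exercise,
      paste(tab$preset, collapse = ", ")
    ))
  }
  cubic_model(
    coefficients = c(row$c0, row$c1, row$c2, row$c3),
    kappa = row$kappa,
    exercise = exercise,
    valid_reps = c(row$min_reps, row$max_reps)
  )
}

# ---- predictors -------------------------------------------------------------

#' Predict 1RM from an RTF observation with a cubic model
#'
#' @param model A [cubic_model()].
#' @param load Load lifted to fatigue, kg (> 0).
#' @param reps Whole repetitions completed to fatigue.
#' @return Predicted 1RM, kg: `rep_percentage(model, reps) * load`.
#' @export
#' @examples
#' predict_cubic(preset_model("pooled"), load = 100, reps = 8)
predict_cubic <- function(model, load, reps) {
  stopifnot(is_cubic_model(model))
  check_positive(load, "load")
  rep_percentage(model, reps) * load
}

#' Predict 1RM from an isometric maximum
#'
#' Multiplies the isometric maximum by the model's isometric coefficient
#' \eqn{\kappa} (the cohort mean of 1RM/ISOM ratios).
#'
#' @param model A [cubic_model()] with a non-`NA` `kappa`.
#' @param isom Isometric maximum, kg (> 0).
#' @return Predicted 1RM, kg.
#' @export
#' @examples
#' predict_isometric(preset_model("pooled"), isom = 100)
predict_isometric <- function(model, isom) {
  stopifnot(is_cubic_model(model))
  if (is.na(model$kappa)) {
    abort_validation("Model has no isometric coefficient; fit one with fit_isometric_coefficient().")
  }
  check_positive(isom, "isom")
  model$kappa * isom
}

#' Combined RTF + isometric 1RM prediction
#'
#' The arithmetic mean of the cubic RTF prediction and the isometric
#' prediction — the "ISOM + r8" predictor when applied to the 5–8 rep zone.
#'
#' @inheritParams predict_cubic
#' @inheritParams predict_isometric
#' @return Predicted 1RM, kg.
#' @export
#' @examples
#' predict_combined(preset_model("pooled"), load = 100, reps = 8, isom = 110)
predict_combined <- function(model, load, reps, isom) {
  (predict_cubic(model, load, reps) + predict_isometric(model, isom)) / 2
}

# ---- methods ----------------------------------------------------------------

#' @export
print.cubic_model <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<cubic_model: %s>\n", x$exercise))
  cat(sprintf("  p(x) = %.8g + %.8g x + %.8g x^2 + %.8g x^3\n", co[1], co[2], co[3], co[4]))
  cat(sprintf("  isometric coefficient kappa: %s\n",
              if (is.na(x$kappa)) "not available" else format(x$kappa, digits = 10)))
  cat(sprintf("  calibrated reps: [%d, %d]\n", x$valid_reps[1], x$valid_reps[2]))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted on %d observations (%d records), residual SD %.3f kg\n",
                x$fit$n_obs, x$fit$n_records, x$fit$sigma))
  }
  invisible(x)
}

#' Tidy a cubic model
#'
#' @param x A [cubic_model()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`c0`..`c3`, `kappa`).
#' @export
tidy.cubic_model <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$coefficients), "kappa"),
    estimate = c(unname(x$coefficients), x$kappa)
  )
}

#' Glance at a cubic model fit
#'
#' @param x A [cubic_model()].
#' @param ... Unused.
#' @return One-row tibble with fit diagnostics (`NA` for bundled presets,
#'   which carry no fit metadata).
#' @export
glance.cubic_model <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    exercise = x$exercise,
    n_records = f$n_records %||% NA_integer_,
    n_obs = f$n_obs %||% NA_integer_,
    rss = f$rss %||% NA_real_,
    sigma = f$sigma %||% NA_real_,
    rank = f$rank %||% NA_integer_,
    condition_number = f$condition_number %||% NA_real_,
    include_anchor = f$include_anchor %||% NA,
    normalize_loss = f$normalize_loss %||% NA
  )
}

#' Plot the rep-percentage curve of a cubic model
#'
#' @param object A [cubic_model()].
#' @param ... Unused.
#' @return A ggplot: `p(x)` over the calibrated repetition range.
#' @export
autoplot.cubic_model <- function(object, ...) {
  grid <- seq(object$valid_reps[1], object$valid_reps[2], by = 0.1)
  df <- tibble::tibble(reps = grid, p = eval_poly(object$coefficients, grid))
  pts <- tibble::tibble(
    reps = seq(object$valid_reps[1], object$valid_reps[2]),
    p = eval_poly(object$coefficients, seq(object$valid_reps[1], object$valid_reps[2]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reps, y = .data$p)) +
    ggplot2::geom_line(colour = "#2171b5") +
    ggplot2::geom_point(data = pts, size = 1.6, colour = "#2171b5") +
    ggplot2::labs(
      x = "repetitions to fatigue",
      y = "rep-percentage multiplier p(x)",
      title = sprintf("Rep-percentage curve (%s)", object$exercise),
      subtitle = "predicted 1RM = p(reps) × load"
    ) +
    ggplot2::theme_minimal()
}
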