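# internal helpers: error classes and argument checks

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "repmax_validation_error", ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "repmax_domain_error", ...)
}

#' Exercises covered by the bundled models
#'
#' The seven machine exercises for which measurements are expected and for
#' which coefficient presets are bundled.
#'
#' @return Character vector of exercise names.
#' @export
#' @examples
#' rm_exercises()
rm_exercises <- function() {
  c(
    "leg_press", "lat_pulls", "triceps_dips", "trunk_extension",
    "trunk_flexion", "leg_extension", "leg_flexion"
  )
}

# reps policy: hard error outside [1, 20], warn outside the model's valid range
check_reps <- function(reps, valid_reps = c(1L, 16L), what = "reps") {
  if (!rlang::is_integerish(reps, finite = TRUE)) {
    abort_validation(sprintf("`%s` must be whole numbers (fractional repetitions are not recorded).", what))
  }
  if (any(reps < 1 | reps > 20)) {
    abort_validation(sprintf("`%s` must lie in [1, 20]; got %s.", what,
                             paste(unique(reps[reps < 1 | reps > 20]), collapse = ", ")))
  }
  out_of_range <- reps < valid_reps[1] | reps > valid_reps[2]
  if (any(out_of_range)) {
    rlang::warn(sprintf(
      "%d repetition value(s) outside the calibrated range [%d, %d]; predictions are extrapolations.",
      sum(out_of_range), valid_reps[1], valid_reps[2]
    ))
  }
  invisible(as.integer(reps))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_validation(sprintf("`%s` must be finite and > 0.", what))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
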