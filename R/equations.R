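#' Literature 1RM prediction equations
#'
#' Registry of the seven repetitions-to-fatigue (RTF) prediction equations
#' evaluated by the package: Brzycki, Epley, Lander, Mayhew, O'Connor, Wathan
#' and the KLW cubic equation for trained postmenopausal women. Each maps a
#' submaximal load and the number of repetitions completed to fatigue to a
#' predicted one-repetition maximum (1RM).
#'
#' Two equations circulate with conflicting coefficients: Epley is sometimes
#' printed with slope 0.333 instead of the canonical 0.0333, and Lander with
#' 2.26123 instead of 2.67123. Both readings are available through `variant`;
#' the canonical form is the default everywhere.
#'
#' @return A tibble with one row per equation and variant: `equation`,
#'   `variant`, and a human-readable `formula`.
#' @export
#' @examples
#' literature_equations()
literature_equations <- function() {
  tibble::tribble(
    ~equation, ~variant,     ~formula,
    "brzycki", "canonical",  "wt / (1.0278 - 0.0278 * reps)",
    "epley",   "canonical",  "wt * (1 + 0.0333 * reps)",
    "epley",   "as_printed", "wt * (1 + 0.333 * reps)",
    "lander",  "canonical",  "100 * wt / (101.3 - 2.67123 * reps)",
    "lander",  "as_printed", "100 * wt / (101.3 - 2.26123 * reps)",
    "mayhew",  "canonical",  "100 * wt / (52.2 + 41.9 * exp(-0.055 * reps))",
    "oconnor", "canonical",  "wt * (1 + 0.025 * reps)",
    "wathan",  "canonical",  "100 * wt / (48.8 + 53.8 * exp(-0.075 * reps))",
    "klw",     "canonical",  "wt * (0.988 - 0.0000584 * reps^3 + 0.0019 * reps^2 + 0.0104 * reps)"
  )
}

literature_equation_names <- function() {
  unique(literature_equations()$equation)
}

# denominator-based equations need a positivity guard; the bound is reported
# in the error so users see where the formula breaks down
check_denominator <- function(den, equation, reps_bound) {
  if (any(den <= 0)) {
    abort_domain(sprintf(
      "The %s equation has a non-positive denominator at the supplied reps (valid only for reps < %s).",
      equation, format(reps_bound)
    ))
  }
}

#' Predict 1RM with a literature equation
#'
#' Evaluates one of the seven published RTF prediction equations at a
#' submaximal load and repetition count. Vectorised over `load` and `reps`.
#'
#' @param load Load lifted to fatigue, kg (> 0).
#' @param reps Whole number of repetitions completed to fatigue, in `[1, 20]`.
#'   A warning is issued outside the calibrated `[1, 16]` range.
#' @param equation One of `"brzycki"`, `"epley"`, `"lander"`, `"mayhew"`,
#'   `"oconnor"`, `"wathan"`, `"klw"`.
#' @param variant `"canonical"` (default) or `"as_printed"`; see
#'   [literature_equations()] for the coefficient conflicts this resolves.
#'   Only Epley and Lander differ between variants.
#' @return Predicted 1RM in kg, same length as the inputs.
#' @export
#' @examples
#' predict_literature(80, 1, "brzycki")   # identity at one rep
#' predict_literature(100, 10, "klw")     # 122.36
#' predict_literature(100, 10, "oconnor") # 125
predict_literature <- function(load, reps,
                               equation = c("brzycki", "epley", "lander", "mayhew",
                                            "oconnor", "wathan", "klw"),
                               variant = c("canonical", "as_printed")) {
  equation <- rlang::arg_match(equation)
  variant <- rlang::arg_match(variant)
  check_positive(load, "load")
  reps <- check_reps(reps)

  switch(equation,
    brzycki = {
      den <- 1.0278 - 0.0278 * reps
      check_denominator(den, "Brzycki", 1.0278 / 0.0278) # reps >= 37 as printed
      load / den
    },
    epley = {
      slope <- if (variant == "as_printed") 0.333 else 0.0333
      load * (1 + slope * reps)
    },
    lander = {
      b <- if (variant == "as_printed") 2.26123 else 2.67123
      den <- 101.3 - b * reps
      check_denominator(den, "Lander", 101.3 / b)
      100 * load / den
    },
    mayhew = 100 * load / (52.2 + 41.9 * exp(-0.055 * reps)),
    oconnor = load * (1 + 0.025 * reps),
    wathan = 100 * load / (48.8 + 53.8 * exp(-0.075 * reps)),
    klw = load * (0.988 - 0.0000584 * reps^3 + 0.0019 * reps^2 + 0.0104 * reps)
  )
}
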