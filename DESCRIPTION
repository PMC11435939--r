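Package: repmax
Title: One-Repetition-Maximum Prediction from Repetitions to Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predict one-repetition-maximum (1RM) strength from submaximal
    repetitions-to-fatigue (RTF) tests and isometric maxima on resistance
    training machines, with a focus on trained older adults. Implements seven
    classic literature prediction equations (Brzycki, Epley, Lander, Mayhew,
    O'Connor, Wathan, KLW), a cubic rep-percentage model with bundled
    exercise-specific coefficient presets, least-squares calibration of new
    equations from tidy measurement data, an isometric-coefficient predictor
    and its combination with RTF, accuracy and test-retest reliability
    reports with normality-gated paired tests, and a seeded synthetic-cohort
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
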