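# repmax

Predict one-repetition-maximum (1RM) strength from submaximal tests.

Direct 1RM testing is the gold standard for prescribing resistance-exercise
intensity, but it is demanding and disruptive — especially for older adults
with osteopenia or osteoporosis, for whom accurate loading matters most.
`repmax` implements the practical alternative: estimating 1RM from
**repetitions to fatigue** (RTF — the number of repetitions completed to
failure at a submaximal load) and, where machines support it, from the
**isometric maximum**.

The package is aimed at exercise scientists and strength coaches who work
with machine-based testing data, and provides:

* the seven classic literature prediction equations (Brzycki, Epley, Lander,
  Mayhew, O'Connor, Wathan, KLW), including the coefficient variants that
  circulate in print;
* a cubic **rep-percentage model**
  `p(x) = c0 + c1·x + c2·x² + c3·x³`, with `1RM ≈ p(reps) × load`,
  bundled with coefficient presets calibrated on trained older adults with
  osteopenia/osteoporosis (a pooled leg-press-derived curve plus six
  exercise-specific curves);
* an isometric predictor `1RM ≈ κ × ISOM`, where κ is the cohort mean of
  1RM/ISOM ratios, and the combined predictor `(ISOM + r8)/2`;
* least-squares calibration of new curves from tidy measurement data
  (`fit_cubic()`, `fit_all_exercises()`);
* accuracy reports in the field's standard shape — mean ± SD of the absolute
  percent difference `100·|predicted − actual|/actual` per exercise ×
  predictor, with Shapiro–Wilk-gated paired t / Wilcoxon signed-rank tests
  (`summarize_accuracy()`, `paired_compare()`);
* test–retest reliability (two-point coefficients of variation, repetition
  agreement) and a fully seeded synthetic-cohort simulator for end-to-end
  validation (`generate_cohort()`, `generate_retest()`).

Everything is tidyverse-native: tibbles in, tibbles out, `tidy()`/`glance()`
methods on fitted models, `autoplot()`/`plot_accuracy()` for figures, and a
thin command-line tool (`inst/cli/repmax.R`) with `predict`, `fit`,
`evaluate` and `simulate` subcommands.

## Worked example

A participant performs 7 repetitions to fatigue at 60 kg on the lat-pull
machine, and holds 65 kg isometrically:

```r
library(repmax)

m <- preset_model("lat_pulls")
predict_cubic(m, load = 60, reps = 7)                # 71.5 kg
predict_isometric(m, isom = 65)                      # 65.0 kg
predict_combined(m, load = 60, reps = 7, isom = 65)  # 68.2 kg
predict_literature(60, 7, "klw")                     # 68.0 kg
```

The cubic curve says 7 reps at 60 kg corresponds to about 71.5 kg of
single-rep strength; the isometric route says 65.0 kg; their mean — the
most accurate predictor for several exercises — says 68.2 kg, close to the
KLW literature equation's 68.0 kg.

How accurate are these predictors? Simulate a realistic 40-person cohort and
score every predictor against the (simulated) actual 1RM:

```r
cohort <- generate_cohort(cohort_config(seed = 1))
acc <- summarize_accuracy(cohort)
dplyr::filter(acc, exercise == "leg_press")
#>   predictor     n pred_mean actual_mean diff_mean diff_sd test          p_value stars
#> 1 r8           36      132.        131.      3.47    2.82 paired t-test  0.170  ""
#> 2 r10          36      133.        131.      4.58    3.54 paired t-test  0.0680 ""
#> 3 r15          36      134.        131.      6.24    4.91 paired t-test  0.0237 "*"
#> 4 isom         36      130.        131.      5.60    3.50 paired t-test  0.691  ""
#> 5 isom_r8      36      131.        131.      3.51    2.39 paired t-test  0.796  ""
```

`diff_mean` is the mean absolute percent difference between predicted and
actual 1RM: the 5–8-rep zone (`r8`, 3.5%) is the most accurate RTF range,
accuracy degrades through `r10` to `r15`, and averaging the isometric and
`r8` predictions (`isom_r8`) is competitive with `r8` alone. `stars` flags
predictors whose predictions differ systematically from the actual values
(`*`/`**`/`***` at p ≤ 0.05/0.01/0.001, test chosen by a Shapiro–Wilk
normality gate and recorded in `test`).

New curves are calibrated with ordinary least squares on the pooled
observations `(reps, load)` with target `w1` (the actual 1RM):

```r
fits <- fit_all_exercises(cohort, mode = "per_exercise")
tidy(fits$model[[1]])     # c0..c3 and kappa
glance(fits$model[[1]])   # n, RSS, rank, condition number
```

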