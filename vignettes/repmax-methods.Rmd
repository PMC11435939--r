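---
title: "Predicting 1RM from repetitions to fatigue: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 1RM from repetitions to fatigue: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repmax)
```

## The problem

The one-repetition maximum (1RM) — the heaviest load that can be lifted
exactly once through the full range of motion — is the reference measure of
dynamic strength and the anchor for resistance-training load prescription.
Testing it directly is effortful and interrupts training, and in populations
with elevated fracture risk (older adults with osteopenia or osteoporosis)
many practitioners prefer to avoid frequent maximal attempts. The practical
substitute is a **repetitions-to-fatigue (RTF)** test: lift a submaximal
load to failure, count the repetitions, and convert (load, reps) into a 1RM
estimate. Machines that support isometric testing add a second submaximal
route: the **isometric maximum (ISOM)**.

`repmax` implements both routes, the calibration machinery to fit them to
new data, and the evaluation statistics the field uses to judge them.

## The cubic rep-percentage model

The central object is a dimensionless **rep-percentage curve**

$$p(x) = c_0 + c_1 x + c_2 x^2 + c_3 x^3,$$

interpreted as the factor by which single-rep strength exceeds the load
liftable for $x$ repetitions:

$$\widehat{1RM} = p(\mathrm{reps}) \times \mathrm{load}.$$

A cubic is the lowest-order polynomial that can follow the empirical shape
of the load–repetition relationship over the 1–16 rep range: near-linear
growth at low repetitions with curvature appearing in the teens. All bundled
presets have a small negative $c_3$, which is harmless inside the
calibrated range but makes far extrapolation unsafe — hence the repetition
policy below.

Three predictors derive from a fitted model:

* **RTF**: $p(\mathrm{reps}) \times \mathrm{load}$ (`predict_cubic()`),
  labelled `r8`, `r10`, `r15` when applied to the observation from the 5–8,
  9–12 or 13–16 rep testing zone;
* **isometric**: $\kappa \times \mathrm{ISOM}$ (`predict_isometric()`),
  where the isometric coefficient $\kappa$ is the cohort mean of
  1RM/ISOM ratios — a deliberately simple one-parameter bridge between the
  two strength modalities;
* **combined**: the arithmetic mean of the two (`predict_combined()`),
  the `isom_r8` predictor when the RTF part comes from the 5–8 zone.

Bundled presets cover seven machine exercises for trained older adults with
reduced bone density: a pooled curve derived from leg-press data (used for
the leg press itself and transferable to other exercises) and six
exercise-specific curves. The registry ships as plain-text YAML
(`inst/extdata/presets.yaml`) and is the same format `write_presets()`
emits for user-fitted models. The six exercise-specific presets share one
printed isometric coefficient (0.9992532650410967); the registry stores it
per exercise as published rather than second-guessing whether a shared
value was intended.

Seven literature equations (Brzycki, Epley, Lander, Mayhew, O'Connor,
Wathan, KLW) are provided for comparison. Two of them circulate with
conflicting coefficients: Epley with slope 0.333 versus the canonical
0.0333 (the former predicts 133% of the load at a *single* repetition,
which cannot be right), and Lander with 2.26123 versus the canonical
2.67123. Both readings are implemented behind a `variant` argument; the
canonical form is the default everywhere and the `as_printed` form exists
for fidelity and sensitivity analysis only.

### Repetition policy

Repetitions are whole numbers — fractional reps are rejected, matching how
RTF tests are recorded. Predictions are served for reps in $[1, 20]$ but
warn outside the calibrated $[1, 16]$ interval; beyond ~20 reps the cubic's
negative leading term bends the curve down and the model is not meaningful,
so that region is a hard error rather than a warning. Predictions are
returned at full floating precision; display rounding (0.1 kg for loads,
0.01% for percent differences) happens only in `write_report()`.

## Fitting

`fit_cubic()` estimates the coefficients by ordinary least squares on the
pooled per-participant observations: minimise

$$\sum_i \left(w_1 - p(r_i)\, w_i\right)^2$$

over all RTF observations $(r_i, w_i)$, where $w_1$ is the record's actual
1RM. The problem is linear in $(c_0,\dots,c_3)$ with regressors
$(w_i, w_i r_i, w_i r_i^2, w_i r_i^3)$ and response $w_1$, and is solved by
QR decomposition — closed-form, deterministic, order-independent, no
regularisation. A design with fewer than four distinct repetition values is
rank-deficient and raises a singular-fit error instead of returning an
arbitrary solution. `glance()` on the fitted model reports the residual SD,
design rank and condition number.

Design choices worth making explicit:

* **Squared loss.** The calibration objective is stated as a least-squares
  problem over residual magnitudes $|w_1 - p(r_i) w_i|$; `repmax` minimises
  the sum of squares, the standard reading of "method of least squares". An
  L1 criterion is out of scope.
* **Anchor.** With `include_anchor = TRUE` (default) each record
  contributes the pseudo-observation (reps = 1, load = $w_1$): the 1RM load
  was, by definition, lifted once. It enters once per record, not once per
  RTF observation. Note that fitted curves generally have $p(1) \neq 1$ —
  the anchor is one residual among many, not a constraint.
* **Pooling and weighting.** Residuals are in absolute kg, so stronger
  participants carry more weight. `normalize_loss = TRUE` divides each
  residual by the record's $w_1$, switching to relative error, as an
  off-by-default sensitivity analysis.
* **Rows, not means.** Fitting uses individual participant rows rather than
  per-exercise aggregated means; with per-participant observation
  quadruples this is the natural reading, and it is what makes the
  singular-fit diagnostics meaningful.

`fit_all_exercises()` implements both calibration strategies: fit one curve
on the leg-press data and transfer it everywhere (`pooled_transfer`), or
fit each exercise independently (`per_exercise`). The isometric coefficient
is always fitted per exercise — it is a property of the exercise's
force-geometry, not of the rep-percentage curve. Exercises whose data
cannot support a fit are returned flagged (`fitted = FALSE` with the
reason), not silently dropped and not fatal to the others.

## Evaluation statistics

Accuracy is summarised per exercise × predictor as the mean ± SD (always
$n-1$ denominator) of the **absolute percent difference**
$100\,|\hat{w} - w_1| / w_1$, alongside a paired test of systematic
difference:

* Shapiro–Wilk on the paired differences gates the test: $p > 0.05$ →
  paired t-test, otherwise Wilcoxon signed-rank. The chosen test is
  recorded in every report row, and `plot_paired_qq()` provides the visual
  companion; Q-Q plots never gate programmatically.
* Wilcoxon conventions: zero differences are dropped, ties are mid-ranked,
  and the exact distribution is used below 25 non-zero pairs (the
  continuity-corrected normal approximation above).
* Degenerate cases are defined, not accidental: all-zero differences
  (below a numerical zero of $10^{-8}$ kg, far under the 0.1 kg resolution
  of any plate stack) return a "none" outcome with $p = 1$; constant
  non-zero differences, where both Shapiro–Wilk and the t-test are
  undefined, fall back to the signed-rank branch.
* Significance stars are `*`/`**`/`***` at $p \le 0.05/0.01/0.001$ —
  the conventional reading.
* Sex comparisons use the classic pooled-variance independent t-test
  (`group_compare()`, with a Welch option).

Test–retest reliability uses the two-point within-subject SD: for trials
$x_1, x_2$, $\mathrm{CV} = 100\,\frac{|x_1 - x_2|/\sqrt 2}{(x_1+x_2)/2}$.
This is the standard reliability convention, but note that some authors use
$|x_1 - x_2|$ divided by the mean, which differs by $\sqrt 2$ — worth
checking before comparing CVs across papers. Repetition agreement is the
cohort mean ± SD of the per-participant $|\Delta \mathrm{reps}|$.

Multiple-testing correction is deliberately absent: the reports mirror the
field's table conventions, which present per-cell tests uncorrected.

## The synthetic cohort

Raw strength-testing cohorts are rarely shareable, so the package carries a
generator (`generate_cohort()`) that emulates the *structure* of a
machine-testing study — per participant × exercise an actual 1RM, an
isometric maximum and one RTF observation per repetition zone — with every
magnitude anchored to published cohort characteristics for trained older
adults. Defaults:

* **Cohort**: n = 40, 17 men / 23 women.
* **Strength**: log-normal, $\log w_1 = \mu_e + \beta\,\mathrm{male} + u_i
  + \varepsilon_{ie}$, with a participant factor $u_i$ (SD 0.15 log-units)
  shared across exercises, a male/female median ratio of 1.7 (typical for
  older adults), and $\mu_e$, $\mathrm{SD}(\varepsilon)$ chosen per
  exercise so the marginal mean and SD match the per-exercise anchors
  (e.g. leg press 129.5 ± 41.1 kg, trunk flexion 48.6 ± 17.7 kg). The
  shared participant factor encodes that strong people are strong across
  exercises; the exact between-exercise correlation is an assumption, as no
  published value exists.
* **RTF observations**: target reps 8/10/15 per zone with ±1-rep jitter at
  probabilities 0.25/0.5/0.25 (giving a two-trial expected absolute
  difference of 0.75 reps, matching the 0.7–0.9-rep retest agreement
  reported for such cohorts), or uniform draws over the full zone; load set
  as $w_1 / p_i(\mathrm{reps})$ times multiplicative noise with SD 2%.
* **Individual curves**: $p_i(r) = p(r)\,e^{\gamma_i (r-1)}$ with
  $\gamma_i \sim N(0, 0.005)$ per participant × exercise. This per-rep
  heterogeneity in repetition tolerance is what makes prediction error grow
  with the repetition zone — with it, the 5–8 zone lands at 3–4% mean
  absolute difference and the 13–16 zone near 6%, reproducing both the
  accuracy band and the r8 < r10 < r15 ordering reported for real cohorts.
  Pure i.i.d. load noise cannot produce that ordering, which is why the
  field restricts RTF testing to low-rep zones.
* **Isometric ratios**: per-record 1RM/ISOM ratio normal around the true
  $\kappa$ with SD 0.08, anchored to the ~5–15% accuracy of isometric-only
  prediction in published tables.
* **Missingness**: each participant misses an exercise with probability
  0.12, landing per-exercise complete n in the low-to-mid thirties, as in
  real cohorts where contraindications and scheduling losses accumulate.

All draws flow through one seed, and standard-normal/uniform variates are
drawn unconditionally and scaled afterwards, so runs differing only in a
noise scale share common random numbers — this is what makes the
noise-monotonicity property (mean error strictly increasing in the load
noise SD) testable without Monte-Carlo slack.

`generate_retest()` simulates the reliability subsample. Its CV parameter
is calibrated so that the *expected cohort mean* of the two-point CV equals
the configured value: the half-normal mean of $|x_1 - x_2|/\sqrt2$ is
$\sigma\sqrt{2/\pi}$, so trial noise is drawn with
$\sigma = \mathrm{cv}\,\sqrt{\pi/2}$. A configured 3.3% therefore *reads
back* as 3.3% through `test_retest_cv()`, keeping the parameter on the
same scale as published CVs.

What the simulator does **not** model: device mechanics, load quantisation
(available as an option, off by default), training adaptation over the
8-month testing window, accumulated fatigue across the test sequence, and
any systematic bias of the true curve family — the generator draws from the
same cubic family the fitter assumes. Passing closed-loop tests therefore
demonstrates correctness of the machinery (identifiability, exact recovery,
calibrated error propagation), not that a cubic is the right model for any
particular device.

## Numerical choices and degenerate inputs

* Exact recovery: on noiseless data with ≥ 4 distinct repetition values the
  LS problem interpolates, and fits reproduce generating coefficients to
  ~1e-12; tests assert 1e-8.
* A fitted or constructed model must have $p > 0$ over its validity range;
  otherwise construction fails with a domain error (a negative
  rep-percentage curve predicts negative strength).
* Validation errors (bad inputs) and domain errors (numerically undefined
  requests) are distinct condition classes, mapped to exit codes 1 and 2 by
  the command-line tool.
* CSV input auto-detects semicolon-delimited, decimal-comma exports
  (common from German-locale spreadsheets) and normalises them; schema
  violations are collected and reported with row numbers in one pass.
* The preset/coefficients registry uses YAML — plain-text, commentable, and
  round-trippable at full double precision (`precision = 17`).

## Problem sizes

The test suite and acceptance script run at desk scale by design:
coefficient recovery on 25–30 simulated records per preset (exact, so size
is immaterial), Monte-Carlo properties at 500–2,000 replicates of n = 30,
CV recovery at n = 10⁴ pairs, and default cohorts of 40 participants ×
7 exercises. These sizes put Monte-Carlo error well inside the asserted
tolerances while keeping the whole suite around a minute.

## Limitations

* The bundled presets were calibrated on machine exercises in one
  population (trained older adults with reduced bone density); transfer to
  free-weight exercises or other populations is plausible but unvalidated
  here.
* The isometric bridge is a single multiplicative coefficient; it ignores
  angle-specificity of isometric strength.
* No uncertainty intervals on fitted coefficients are produced, and no
  hierarchical (per-participant) modelling is attempted — the calibration
  pools residuals in kg across participants.
* Percent differences are computed per participant and then averaged;
  tables computed from group means would differ slightly.
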