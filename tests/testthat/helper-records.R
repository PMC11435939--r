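# fixtures built in code

# records whose RTF observations satisfy w1 = p(reps) * load exactly
make_noiseless_records <- function(model, n = 30, reps = c(1, 6, 10, 15),
                                   w1 = seq(50, 150, length.out = n)) {
  p <- function(r) {
    co <- model$coefficients
    co[1] + co[2] * r + co[3] * r^2 + co[4] * r^3
  }
  tibble::tibble(
    participant_id = sprintf("S%03d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    exercise = model$exercise,
    one_rm = w1,
    isom = if (is.na(model$kappa)) NA_real_ else w1 / model$kappa,
    rtf = lapply(w1, function(w) {
      tibble::tibble(
        zone = rep_zone(reps),
        reps = as.integer(reps),
        load = w / p(reps)
      )
    })
  )
}

# residual sum of squares of the cubic objective for arbitrary coefficients
cubic_rss <- function(records, coefficients, include_anchor = FALSE) {
  obs <- tidyr::unnest(records[, c("one_rm", "rtf")], "rtf")
  if (include_anchor) {
    obs <- dplyr::bind_rows(
      obs,
      dplyr::transmute(records, one_rm = one_rm, reps = 1L, load = one_rm)
    )
  }
  p <- coefficients[1] + coefficients[2] * obs$reps +
    coefficients[3] * obs$reps^2 + coefficients[4] * obs$reps^3
  sum((obs$one_rm - p * obs$load)^2)
}

# all-noise-off configuration: the generator becomes a deterministic encoder
noiseless_config <- function(seed = 5, ...) {
  cohort_config(
    sigma_load = 0, sigma_kappa = 0, sigma_curve = 0,
    rep_jitter_probs = c(0, 1, 0), missing_rate = 0, seed = seed, ...
  )
}
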