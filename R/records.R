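# strength records: one row per participant x exercise, with the actual 1RM,
# the isometric maximum (optional) and a nested tibble of RTF observations

new_strength_records <- function(x) {
  class(x) <- c("strength_records", class(tibble::tibble()))
  x
}

#' Infer the nominal repetition zone of an RTF observation
#'
#' Zones follow the testing protocol: `r8` = 5–8 reps, `r10` = 9–12,
#' `r15` = 13–16. Repetitions outside all zones return `NA`.
#'
#' @param reps Whole repetition counts.
#' @return Character vector of `"r8"`, `"r10"`, `"r15"` or `NA`.
#' @export
#' @examples
#' rep_zone(c(5, 9, 16, 2))
rep_zone <- function(reps) {
  dplyr::case_when(
    reps >= 5 & reps <= 8 ~ "r8",
    reps >= 9 & reps <= 12 ~ "r10",
    reps >= 13 & reps <= 16 ~ "r15",
    TRUE ~ NA_character_
  )
}

#' Group a tidy measurement table into strength records
#'
#' Collapses a long measurement table (one row per participant x exercise x
#' measurement; see [read_measurements()] for the schema) into one row per
#' participant x exercise, with columns `one_rm`, `isom` and a nested `rtf`
#' tibble of repetitions-to-fatigue observations (`zone`, `reps`, `load`).
#' Where several trials of a measurement exist, the first trial is kept.
#'
#' @param measurements A tibble with columns `participant_id`, `sex`,
#'   `exercise`, `kind` (`"1RM"`, `"ISOM"`, `"RTF"`), `load`, and `reps` for
#'   RTF rows; optional `zone` and `trial`.
#' @return A `strength_records` tibble.
#' @export
as_strength_records <- function(measurements) {
  m <- validate_measurements(measurements)
  m <- m |>
    dplyr::group_by(.data$participant_id, .data$exercise, .data$kind, .data$zone) |>
    dplyr::filter(.data$trial == min(.data$trial)) |>
    dplyr::ungroup()

  nested <- m |>
    dplyr::group_by(.data$participant_id, .data$sex, .data$exercise) |>
    dplyr::summarise(
      one_rm = .data$load[.data$kind == "1RM"][1],
      isom = .data$load[.data$kind == "ISOM"][1],
      rtf = {
        idx <- .data$kind == "RTF"
        z <- .data$zone[idx]
        rp <- as.integer(.data$reps[idx])
        ld <- .data$load[idx]
        list(tibble::tibble(zone = z, reps = rp, load = ld))
      },
      .groups = "drop"
    )
  if (any(is.na(nested$one_rm))) {
    missing <- nested[is.na(nested$one_rm), c("participant_id", "exercise")]
    rlang::warn(sprintf(
      "%d participant x exercise group(s) lack a 1RM measurement and are dropped (e.g. %s / %s).",
      nrow(missing), missing$participant_id[1], missing$exercise[1]
    ))
    nested <- nested[!is.na(nested$one_rm), , drop = FALSE]
  }
  new_strength_records(nested)
}

#' Flatten strength records back into a tidy measurement table
#'
#' Inverse of [as_strength_records()]: emits one `1RM` row, one `ISOM` row
#' (when present) and one `RTF` row per observation, for each participant x
#' exercise.
#'
#' @param records A `strength_records` tibble.
#' @return A tibble in the measurement-table schema (`trial` is 1 throughout).
#' @export
records_to_measurements <- function(records) {
  stopifnot(is.data.frame(records))
  purrr::pmap_dfr(records, function(participant_id, sex, exercise, one_rm, isom, rtf, ...) {
    base <- tibble::tibble(
      participant_id = participant_id, sex = sex, exercise = exercise,
      kind = "1RM", zone = NA_character_, load = one_rm, reps = NA_integer_, trial = 1L
    )
    if (!is.na(isom)) {
      base <- dplyr::bind_rows(base, tibble::tibble(
        participant_id = participant_id, sex = sex, exercise = exercise,
        kind = "ISOM", zone = NA_character_, load = isom, reps = NA_integer_, trial = 1L
      ))
    }
    if (nrow(rtf) > 0) {
      base <- dplyr::bind_rows(base, tibble::tibble(
        participant_id = participant_id, sex = sex, exercise = exercise,
        kind = "RTF", zone = rtf$zone, load = rtf$load, reps = rtf$reps, trial = 1L
      ))
    }
    base
  })
}

# schema validation with row numbers; collects all offending rows before
# aborting so a single pass reports every problem
validate_measurements <- function(m) {
  if (!is.data.frame(m)) abort_validation("Measurements must be a data frame.")
  m <- tibble::as_tibble(m)
  names(m) <- tolower(names(m))
  required <- c("participant_id", "sex", "exercise", "kind", "load")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("Missing required column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  if (!"reps" %in% names(m)) m$reps <- NA_integer_
  if (!"trial" %in% names(m)) m$trial <- 1L
  if (!"zone" %in% names(m)) m$zone <- NA_character_
  m$trial <- dplyr::coalesce(as.integer(m$trial), 1L)

  m$kind <- toupper(as.character(m$kind))
  m$sex <- tolower(as.character(m$sex))
  m$exercise <- tolower(as.character(m$exercise))
  row <- seq_len(nrow(m))

  problems <- character()
  bad <- function(which, msg) {
    if (any(which)) {
      problems <<- c(problems, sprintf("%s (rows %s)", msg,
                                       paste(utils::head(row[which], 10), collapse = ", ")))
    }
  }
  bad(!m$kind %in% c("1RM", "ISOM", "RTF"), "kind must be one of 1RM, ISOM, RTF")
  bad(!m$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  bad(!m$exercise %in% rm_exercises(), sprintf("exercise must be one of %s",
                                               paste(rm_exercises(), collapse = ", ")))
  load_num <- suppressWarnings(as.numeric(m$load))
  bad(!is.finite(load_num) | load_num <= 0, "load must be a positive number")
  m$load <- load_num
  is_rtf <- m$kind == "RTF"
  reps_num <- suppressWarnings(as.numeric(m$reps))
  bad(is_rtf & (!is.finite(reps_num) | reps_num < 1 | reps_num > 20 | reps_num %% 1 != 0),
      "RTF rows need a whole reps value in [1, 20]")
  if (length(problems) > 0) {
    abort_validation(paste0("Invalid measurement table:\n- ", paste(problems, collapse = "\n- ")))
  }
  m$reps <- ifelse(is_rtf, as.integer(reps_num), NA_integer_)
  m$zone <- ifelse(is_rtf,
                   ifelse(is.na(m$zone), rep_zone(m$reps), tolower(as.character(m$zone))),
                   NA_character_)

  dup <- duplicated(m[, c("participant_id", "exercise", "kind", "zone", "trial")])
  if (any(dup)) {
    abort_validation(sprintf(
      "Duplicate (participant, exercise, kind, zone, trial) measurement(s) at rows %s.",
      paste(row[dup], collapse = ", ")
    ))
  }
  m
}
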