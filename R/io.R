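# CSV measurement tables and report output

#' Read a measurement CSV into strength records
#'
#' Expected schema (header required, UTF-8): columns `participant_id`, `sex`
#' (`female`/`male`), `exercise` (see [rm_exercises()]), `kind` (`1RM`,
#' `ISOM`, `RTF`), `load` (kg, positive, `.` decimal separator), `reps`
#' (whole number, RTF rows only), and optional `zone` (`r8`/`r10`/`r15`) and
#' `trial`. Semicolon-delimited files with decimal commas (common in German
#' spreadsheet exports) are auto-detected and normalised. Schema violations
#' are reported with their row numbers; duplicated
#' (participant, exercise, kind, zone, trial) measurements are an error.
#'
#' @param path CSV file path.
#' @return A `strength_records` tibble (see [as_strength_records()]).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  semicolon <- lengths(regmatches(first, gregexpr(";", first))) >
    lengths(regmatches(first, gregexpr(",", first)))
  m <- if (semicolon) {
    readr::read_csv2(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  as_strength_records(m)
}

#' Write strength records (or a measurement table) to CSV
#'
#' @param data A `strength_records` tibble or a long measurement table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  m <- if ("rtf" %in% names(data)) records_to_measurements(data) else tibble::as_tibble(data)
  readr::write_csv(m, path)
  invisible(path)
}

round_report <- function(reports) {
  kg <- c("pred_mean", "pred_sd", "actual_mean", "actual_sd")
  pct <- c("diff_mean", "diff_sd")
  reports |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(kg), ~ round(.x, 1)),
      dplyr::across(dplyr::any_of(pct), ~ round(.x, 2)),
      dplyr::across(dplyr::any_of(c("statistic", "p_value")), ~ signif(.x, 4))
    )
}

#' Write an accuracy report to CSV or markdown
#'
#' One row per exercise x predictor, mirroring the accuracy-table layout:
#' predicted mean ± SD, actual mean ± SD, mean ± SD of the absolute percent
#' difference, paired-test result and significance stars. Loads are rounded
#' to 0.1 kg and percent differences to 0.01% for display; full precision
#' stays in the [summarize_accuracy()] tibble.
#'
#' @param reports An `rm_accuracy` tibble from [summarize_accuracy()].
#' @param path Output file path.
#' @param format `"csv"` (default) or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, format = c("csv", "markdown")) {
  format <- rlang::arg_match(format)
  if (!is.data.frame(reports)) abort_validation("`reports` must be a data frame.")
  cols <- c("exercise", "predictor", "n", "pred_mean", "pred_sd", "actual_mean",
            "actual_sd", "diff_mean", "diff_sd", "test", "statistic", "p_value", "stars")
  if (nrow(reports) == 0) {
    empty <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(cols)), cols
    ))
    if (format == "csv") {
      readr::write_csv(empty, path)
    } else {
      writeLines(paste0("| ", paste(cols, collapse = " | "), " |"), path)
    }
    return(invisible(path))
  }
  out <- round_report(reports[, intersect(cols, names(reports)), drop = FALSE])
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    fmt_pm <- function(m, s) ifelse(is.na(m), "-", sprintf("%s ± %s", format(m), format(s)))
    md <- out |>
      dplyr::mutate(
        predicted = fmt_pm(.data$pred_mean, .data$pred_sd),
        actual = fmt_pm(.data$actual_mean, .data$actual_sd),
        rel_diff_pct = ifelse(is.na(.data$diff_mean), "-",
                              sprintf("%.2f ± %.2f %s", .data$diff_mean,
                                      .data$diff_sd, dplyr::coalesce(.data$stars, ""))),
        .keep = "unused"
      ) |>
      dplyr::select(dplyr::any_of(c("exercise", "predictor", "n", "predicted",
                                    "actual", "rel_diff_pct", "test")))
    header <- paste0("| ", paste(names(md), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(md)), collapse = "|"), "|")
    body <- apply(md, 1, function(r) paste0("| ", paste(trimws(r), collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  invisible(path)
}
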