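# Delimited-text interchange: tab-separated with header row, ISO-8601 dates,
# empty fields for missing values, 1-based closed period indices.

write_tsv_file <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  is_date <- vapply(df, inherits, logical(1), what = "Date")
  df[is_date] <- lapply(df[is_date], format, "%Y-%m-%d")
  is_time <- vapply(df, inherits, logical(1), what = "POSIXct")
  df[is_time] <- lapply(df[is_time], format, "%Y-%m-%dT%H:%M:%S")
  is_lgl <- vapply(df, is.logical, logical(1))
  df[is_lgl] <- lapply(df[is_lgl], as.integer)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             na.strings = "", stringsAsFactors = FALSE)
}

check_schema <- function(df, required, what, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("%s file '%s' is missing required column(s): %s",
          what, path, paste(missing_cols, collapse = ", "))
  df
}

check_rows <- function(ok, what, column) {
  if (!all(ok)) {
    bad <- which(!ok)
    stopf("%s: invalid values in column '%s' at row(s) %s", what, column,
          paste(head(bad, 10), collapse = ", "))
  }
}

#' Read and write outcome panel tables
#'
#' The panel interchange format is tab-separated text with header columns
#' `child_id`, `sector`, `group`, `period` (1-based month index), `x`
#' (exposure indicator, may be empty for dropped transition periods) and `y`
#' (binary ALRI indicator).
#'
#' @param panel panel data frame.
#' @param path file path.
#' @return `read_panel` returns the validated panel data frame.
#' @export
write_panel <- function(panel, path) write_tsv_file(panel, path)

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  d <- check_schema(read_tsv_file(path),
                    c("child_id", "sector", "group", "period", "x", "y"),
                    "panel", path)
  check_rows(!is.na(d$y) & d$y %in% c(0, 1), "panel", "y")
  check_rows(is.na(d$x) | d$x %in% c(0, 1), "panel", "x")
  check_rows(!is.na(d$period) & d$period >= 1, "panel", "period")
  d
}

#' Read and write daily symptom diary tables
#'
#' Tab-separated with columns `child_id`, `date` (ISO-8601) and 0/1 symptom
#' columns `fever`, `fast_difficult_breathing`, `persistent_cough`,
#' `wheezing`, `watery_stool`, `ear_discharge`; missing reports are empty
#' fields.
#'
#' @param diary diary data frame.
#' @param path file path.
#' @export
write_diary <- function(diary, path) write_tsv_file(diary, path)

#' @rdname write_diary
#' @export
read_diary <- function(path) {
  d <- check_schema(read_tsv_file(path),
                    c("child_id", "date", "fever", "fast_difficult_breathing"),
                    "diary", path)
  d$date <- as.Date(d$date)
  check_rows(!is.na(d$date), "diary", "date")
  for (cl in intersect(names(d), c("fever", "fast_difficult_breathing",
                                   "persistent_cough", "wheezing",
                                   "watery_stool", "ear_discharge"))) {
    check_rows(is.na(d[[cl]]) | d[[cl]] %in% c(0, 1), "diary", cl)
    d[[cl]] <- as.logical(d[[cl]])
  }
  d
}

#' Read and write 10-second logger traces
#'
#' Tab-separated with columns `timestamp` (ISO-8601), `value`,
#' `relative_humidity`, `temperature`. The concentration units
#' (`ug/m3` for PM2.5 or `ppm` for CO) are echoed in a header comment and
#' restored as `attr(, "units")` on reading.
#'
#' @param trace logger data frame.
#' @param path file path.
#' @param units concentration units label.
#' @export
write_logger <- function(trace, path, units = "ug/m3") {
  write_tsv_file(trace, path, comments = sprintf("value_units: %s", units))
}

#' @rdname write_logger
#' @export
read_logger <- function(path) {
  first <- readLines(path, n = 1L)
  units <- if (grepl("^# value_units:", first))
    sub("^# value_units:\\s*", "", first) else NA_character_
  d <- check_schema(read_tsv_file(path), c("timestamp", "value"),
                    "logger", path)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  check_rows(!is.na(d$timestamp), "logger", "timestamp")
  check_rows(is.na(d$value) | d$value >= 0, "logger", "value")
  attr(d, "units") <- units
  d
}

#' Write an episode table
#'
#' @param episodes episode table from [detect_episodes()] /
#'   [classify_severe()].
#' @param path file path.
#' @export
write_episodes <- function(episodes, path) write_tsv_file(episodes, path)

#' Serialize and restore a stepped-wedge design as a YAML config
#'
#' @param design an [sw_design()].
#' @param path file path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "sw_design"))
  yaml::write_yaml(list(
    n_groups = design$n_groups,
    sectors_per_group = design$sectors_per_group,
    pre_months = design$pre_months,
    wedge_months = design$wedge_months,
    post_months = design$post_months,
    wedge_order = design$wedge_order,
    transition = design$transition,
    period_unit = design$period_unit
  ), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  sw_design(n_groups = cfg$n_groups %||% 12,
            sectors_per_group = cfg$sectors_per_group %||% 4,
            pre_months = cfg$pre_months %||% 6,
            wedge_months = cfg$wedge_months %||% 12,
            post_months = cfg$post_months %||% 6,
            wedge_order = cfg$wedge_order,
            transition = cfg$transition %||% "unexposed",
            period_unit = cfg$period_unit %||% "month")
}

#' Write phase-two arm assignments
#'
#' @param assignments data frame from [randomize_phase2()].
#' @param path file path.
#' @export
write_assignments <- function(assignments, path)
  write_tsv_file(assignments[, c("household_id", "stratum", "arm")], path)
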