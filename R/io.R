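#' Read daily step series from long-format CSV
#'
#' Expects columns `participant_id`, `date` (ISO-8601), `steps`, and
#' optionally `wear_minutes`. Rows may be unsorted. Each participant's series
#' is densified to a gap-free calendar grid between their first and last
#' recorded date; days absent from the file become explicit missing entries
#' (`steps = NA`). Missing steps may also be encoded as empty fields.
#'
#' @param path Path to a CSV file.
#' @return Tibble with columns `participant_id`, `date`, `day` (1-based study
#'   day), `steps`, and `wear_minutes` if present in the file.
#' @export
read_step_series <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(raw, c("participant_id", "date", "steps"), basename(path))

  if (!inherits(raw$date, "Date")) {
    parsed <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(raw$date))
    if (length(bad) > 0) {
      stop_stepdyn(sprintf(
        "non-ISO-8601 date in row %d: '%s'", bad[1], raw$date[bad[1]]
      ))
    }
    raw$date <- parsed
  }
  raw$steps <- as.numeric(raw$steps)
  neg <- which(!is.na(raw$steps) & raw$steps < 0)
  if (length(neg) > 0) {
    stop_stepdyn(sprintf("negative step count in row %d", neg[1]))
  }
  dup <- raw %>%
    mutate(.row = row_number()) %>%
    group_by(.data$participant_id, .data$date) %>%
    filter(n() > 1) %>%
    ungroup()
  if (nrow(dup) > 0) {
    stop_stepdyn(sprintf(
      "duplicate (participant, date) pair at file line %d: %s / %s",
      dup$.row[2] + 1L, dup$participant_id[1], format(dup$date[1])
    ))
  }

  has_wear <- "wear_minutes" %in% names(raw)
  keep <- c("participant_id", "date", "steps", if (has_wear) "wear_minutes")
  raw %>%
    select(all_of(keep)) %>%
    group_by(.data$participant_id) %>%
    tidyr::complete(date = seq(min(.data$date), max(.data$date), by = "day")) %>%
    arrange(.data$date, .by_group = TRUE) %>%
    mutate(day = row_number()) %>%
    ungroup() %>%
    select(all_of(c("participant_id", "date", "day", "steps", if (has_wear) "wear_minutes")))
}

#' Write step series to long-format CSV
#'
#' Inverse of [read_step_series()] on the dense grid: comma-separated, UTF-8,
#' header, ISO-8601 dates, missing steps as empty fields.
#'
#' @param data Tibble with `participant_id`, `date`, `steps` and optionally
#'   `wear_minutes`.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_step_series <- function(data, path) {
  check_columns(data, c("participant_id", "date", "steps"), "series data")
  keep <- c(
    "participant_id", "date", "steps",
    if ("wear_minutes" %in% names(data)) "wear_minutes"
  )
  readr::write_csv(data[, keep], path, na = "")
  invisible(data)
}

#' Write a ground-truth transition table to CSV
#'
#' Sidecar for simulated cohorts: one row per true breakpoint.
#'
#' @param truth Tibble with `participant_id`, `breakpoint_day`, `direction`,
#'   `pre_level`, `post_level` (as from [simulate_cohort()]).
#' @param path Output CSV path.
#' @return `truth`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  check_columns(
    truth,
    c("participant_id", "breakpoint_day", "direction", "pre_level", "post_level"),
    "ground truth"
  )
  readr::write_csv(truth, path, na = "")
  invisible(truth)
}
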