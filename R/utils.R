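#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abort with a consistent class
#' @noRd
stop_stepdyn <- function(msg, class = "stepdyn_error") {
  rlang::abort(msg, class = class)
}

#' Check that a data frame has the required columns
#' @noRd
check_columns <- function(data, cols, what = "data") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_stepdyn(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(data)
}

#' Derive a reproducible 32-bit participant seed from a cohort seed
#' @noRd
participant_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647)
}

#' Is a calendar date a weekend day?
#' @noRd
is_weekend <- function(date) {
  format(date, "%u") %in% c("6", "7")
}
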