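#' Apply the daily wear-time validity rule
#'
#' Days with fewer than `min_wear_minutes` minutes of valid device wear are
#' not trusted and their step counts are set to missing. If the data carry no
#' `wear_minutes` column (e.g. synthetic cohorts, which have no wear channel)
#' the filter is a no-op with a warning.
#'
#' @param data Long person-day tibble with `participant_id`, `day`, `steps`
#'   and optionally `wear_minutes`.
#' @param min_wear_minutes Minimum valid wear minutes per day (default 600).
#' @return `data` with sub-threshold days set to `NA` steps.
#' @export
apply_wear_validity <- function(data, min_wear_minutes = 600) {
  check_columns(data, c("participant_id", "day", "steps"), "series data")
  if (!("wear_minutes" %in% names(data))) {
    warning("no wear_minutes column; wear-time validity filter skipped",
      call. = FALSE
    )
    return(data)
  }
  invalid <- !is.na(data$wear_minutes) & data$wear_minutes < min_wear_minutes
  n_inv <- sum(invalid & !is.na(data$steps))
  if (n_inv > 0) {
    message(sprintf(
      "wear-time validity: %d observed day(s) below %d wear minutes set to missing",
      n_inv, min_wear_minutes
    ))
  }
  data$steps[invalid] <- NA_real_
  data
}

#' Check study-inclusion criteria per participant
#'
#' A participant is included when their series spans at least `min_days`
#' calendar days and strictly less than `max_missing_frac` of those days are
#' missing.
#'
#' @param data Long person-day tibble with `participant_id`, `day`, `steps`
#'   (wear-time validity already applied).
#' @param min_days Minimum series length in days (default 90).
#' @param max_missing_frac Maximum tolerated missing fraction, exclusive
#'   (default 0.20: exactly 20% missing is excluded).
#' @return Tibble with one row per participant: `participant_id`, `n_days`,
#'   `n_missing`, `missing_frac`, `included`, `reasons`.
#' @export
check_inclusion <- function(data, min_days = 90, max_missing_frac = 0.20) {
  check_columns(data, c("participant_id", "day", "steps"), "series data")
  if (nrow(data) == 0) stop_stepdyn("empty series data")
  data %>%
    group_by(.data$participant_id) %>%
    summarise(
      n_days = n(),
      n_missing = sum(is.na(.data$steps)),
      .groups = "drop"
    ) %>%
    mutate(
      missing_frac = .data$n_missing / .data$n_days,
      included = .data$n_days >= min_days & .data$missing_frac < max_missing_frac,
      reasons = purrr::map2_chr(
        .data$n_days, .data$missing_frac,
        function(nd, mf) {
          r <- c(
            if (nd < min_days) sprintf("min_days (%d < %d)", nd, min_days),
            if (mf >= max_missing_frac) {
              sprintf("max_missing_frac (%.3f >= %.2f)", mf, max_missing_frac)
            }
          )
          paste(r, collapse = "; ")
        }
      )
    )
}

#' Impute missing days with a local-level Kalman smoother
#'
#' Fits a local-level structural state-space model (random-walk level plus
#' observation noise) to each participant's series by maximum likelihood and
#' replaces missing days with the smoothed state estimate, clipped at zero.
#' Observed values are never altered. If the optimizer fails or the series is
#' degenerate (e.g. constant), the fallback is linear interpolation with a
#' warning.
#'
#' @param data Long person-day tibble with `participant_id`, `day`, `steps`
#'   (missing days as `NA`).
#' @return `data` with no missing `steps` and a logical `imputed` column
#'   marking exactly the formerly missing days.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   participant_id = "P1", day = 1:30,
#'   steps = c(rep(8000, 10), NA, NA, rep(8000, 18))
#' )
#' imp <- impute_kalman(d)
#' sum(imp$imputed)
impute_kalman <- function(data) {
  check_columns(data, c("participant_id", "day", "steps"), "series data")
  data %>%
    group_by(.data$participant_id) %>%
    group_split() %>%
    purrr::map(impute_kalman_one) %>%
    bind_rows()
}

#' @noRd
impute_kalman_one <- function(d) {
  y <- d$steps
  miss <- is.na(y)
  d$imputed <- miss
  if (!any(miss)) {
    return(d)
  }
  if (all(miss)) stop_stepdyn(sprintf("all days missing for %s", d$participant_id[1]))
  if (sum(!miss) < 2) {
    stop_stepdyn(sprintf("fewer than 2 observed days for %s", d$participant_id[1]))
  }
  # StructTS needs a non-missing first value: fit on the observed core and
  # back/forecast boundary gaps with the boundary smoothed level (the exact
  # local-level treatment, since the level is a random walk)
  obs_idx <- which(!miss)
  lo <- obs_idx[1]
  hi <- obs_idx[length(obs_idx)]
  smoothed <- tryCatch(
    {
      fit <- StructTS(stats::ts(y[lo:hi]), type = "level")
      core <- as.numeric(tsSmooth(fit)[, 1])
      out <- rep(NA_real_, length(y))
      out[lo:hi] <- core
      if (lo > 1) out[seq_len(lo - 1)] <- core[1]
      if (hi < length(y)) out[(hi + 1):length(y)] <- core[length(core)]
      out
    },
    error = function(e) NULL
  )
  if (is.null(smoothed) || any(!is.finite(smoothed[miss]))) {
    warning(sprintf(
      "local-level Kalman fit failed for %s; falling back to linear interpolation",
      d$participant_id[1]
    ), call. = FALSE)
    smoothed <- approx(d$day[!miss], y[!miss], xout = d$day, rule = 2)$y
  }
  y[miss] <- pmax(0, smoothed[miss])
  d$steps <- y
  d
}

#' Prepare raw step series for analysis
#'
#' The standard preparation chain: wear-time validity filter, inclusion
#' criteria, then Kalman imputation of the retained participants. The order is
#' validity first, so invalid days count toward the missing fraction.
#' Re-running on its own output is the identity.
#'
#' @param data Long person-day tibble (from [read_step_series()] or
#'   [simulate_cohort()]).
#' @param min_wear_minutes Passed to [apply_wear_validity()].
#' @param min_days,max_missing_frac Passed to [check_inclusion()].
#' @return Imputed tibble of included participants, with the inclusion report
#'   attached as attribute `"inclusion"` (also see [check_inclusion()]).
#' @export
prepare_steps <- function(data, min_wear_minutes = 600, min_days = 90,
                          max_missing_frac = 0.20) {
  if ("wear_minutes" %in% names(data)) {
    data <- apply_wear_validity(data, min_wear_minutes)
  }
  report <- check_inclusion(data, min_days, max_missing_frac)
  kept <- report$participant_id[report$included]
  if (length(kept) < nrow(report)) {
    message(sprintf(
      "inclusion: %d of %d participant(s) retained",
      length(kept), nrow(report)
    ))
  }
  out <- data %>%
    filter(.data$participant_id %in% kept) %>%
    impute_kalman()
  attr(out, "inclusion") <- report
  out
}
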