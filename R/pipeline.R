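#' Descriptive summary of a cohort and its detected events
#'
#' @param steps Person-day tibble (pre-imputation, so missing days are
#'   counted, or imputed with an `imputed` column).
#' @param events Event tibble from [detect_transitions()].
#' @return One-row tibble: participant count, series-length and missing-day
#'   descriptives, daily-step descriptives, events per participant, gain/loss
#'   counts, mean absolute level change (overall and by direction), and the
#'   mean inter-event gap in days (pooled over consecutive same-participant
#'   event pairs).
#' @export
summarize_cohort <- function(steps, events) {
  check_columns(steps, c("participant_id", "day", "steps"), "series data")
  miss_col <- if ("imputed" %in% names(steps)) {
    steps$imputed
  } else {
    is.na(steps$steps)
  }
  per <- steps %>%
    mutate(.miss = miss_col) %>%
    group_by(.data$participant_id) %>%
    summarise(n_days = n(), n_missing = sum(.data$.miss), .groups = "drop")
  ev_per <- per %>%
    left_join(
      events %>% group_by(.data$participant_id) %>% summarise(n_events = n(), .groups = "drop"),
      by = "participant_id"
    ) %>%
    mutate(n_events = tidyr::replace_na(.data$n_events, 0L))
  gaps <- events %>%
    group_by(.data$participant_id) %>%
    arrange(.data$day, .by_group = TRUE) %>%
    summarise(gaps = list(diff(.data$day)), .groups = "drop") %>%
    pull(.data$gaps) %>%
    unlist()

  tibble(
    n_participants = nrow(per),
    mean_length_days = mean(per$n_days),
    min_length_days = min(per$n_days),
    max_length_days = max(per$n_days),
    mean_missing_days = mean(per$n_missing),
    min_missing_days = min(per$n_missing),
    max_missing_days = max(per$n_missing),
    mean_daily_steps = mean(steps$steps, na.rm = TRUE),
    median_daily_steps = median(steps$steps, na.rm = TRUE),
    mean_events_per_participant = mean(ev_per$n_events),
    min_events_per_participant = min(ev_per$n_events),
    max_events_per_participant = max(ev_per$n_events),
    n_events = nrow(events),
    n_gains = sum(events$direction == "gain"),
    n_losses = sum(events$direction == "loss"),
    mean_abs_delta_steps = if (nrow(events) > 0) mean(abs(events$delta_steps)) else NA_real_,
    mean_abs_delta_gains = if (any(events$direction == "gain")) {
      mean(abs(events$delta_steps[events$direction == "gain"]))
    } else NA_real_,
    mean_abs_delta_losses = if (any(events$direction == "loss")) {
      mean(abs(events$delta_steps[events$direction == "loss"]))
    } else NA_real_,
    mean_interevent_gap_days = if (length(gaps) > 0) mean(gaps) else NA_real_
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates preparation, transition detection, dynamic-complexity
#' computation and the three event-history models (any event, gains only,
#' losses only) on either supplied data or a freshly simulated cohort.
#'
#' @param data Long person-day tibble (e.g. from [read_step_series()] or
#'   `simulate_cohort()$steps`). If `NULL`, a cohort is simulated from
#'   `config`.
#' @param config A [cohort_config()] used when `data` is `NULL`.
#' @param detect_params A [detection_params()].
#' @param complexity_pars A [complexity_params()].
#' @param min_wear_minutes,min_days,max_missing_frac Preparation settings, see
#'   [prepare_steps()].
#' @param fit_models Fit the event-history models (default `TRUE`). With zero
#'   detected events the model stage is skipped with a notice.
#' @param out_dir Optional directory; when given, the events, segmentation,
#'   complexity trace, summary and model reports are written as CSV/JSON.
#' @param quiet Suppress progress messages.
#' @return An object of class `stepdyn_pipeline`: list with `summary`,
#'   `inclusion`, `steps` (imputed), `events`, `segmentation`, `trace`,
#'   `event_table`, `models` (named list `both`/`gains`/`losses`, possibly
#'   `NULL`), and the parameter objects.
#' @export
run_pipeline <- function(data = NULL, config = NULL,
                         detect_params = detection_params(),
                         complexity_pars = complexity_params(),
                         min_wear_minutes = 600, min_days = 90,
                         max_missing_frac = 0.20,
                         fit_models = TRUE, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_stepdyn(sprintf("[stage: %s] %s", name, conditionMessage(e)))
    })
  }

  if (is.null(data)) {
    config <- config %||% cohort_config()
    say("simulating cohort (n = %d, seed = %d)", config$n_participants, config$seed)
    cohort <- stage("simulate", simulate_cohort(config))
    data <- cohort$steps
  }

  say("preparing: wear validity, inclusion, Kalman imputation")
  prepared <- stage("prepare", prepare_steps(
    data,
    min_wear_minutes = min_wear_minutes,
    min_days = min_days, max_missing_frac = max_missing_frac
  ))
  inclusion <- attr(prepared, "inclusion")

  say("detecting sudden gains and losses (threshold %.0f%% of median, >= %d-day regimes)",
    100 * detect_params$threshold_frac, detect_params$min_segment_days)
  events <- stage("detect", detect_transitions(prepared, detect_params))
  segmentation <- attr(events, "segmentation")

  say("computing dynamic complexity (%d-day window, lag %d)",
    complexity_pars$window_days, complexity_pars$ldc_lag_days)
  trace <- stage("complexity", complexity_trace(prepared, complexity_pars))

  event_table <- stage("event_table", build_event_table(trace, events))
  summary <- summarize_cohort(prepared, events)

  models <- list(both = NULL, gains = NULL, losses = NULL)
  if (fit_models) {
    if (nrow(events) == 0) {
      message("no events detected; model stage skipped")
    } else {
      for (oc in names(models)) {
        say("fitting event-history model: %s", oc)
        models[[oc]] <- tryCatch(
          fit_event_model(event_table, outcome = oc),
          error = function(e) {
            warning(sprintf("model '%s' failed: %s", oc, conditionMessage(e)),
              call. = FALSE
            )
            NULL
          }
        )
      }
    }
  }

  result <- structure(
    list(
      summary = summary, inclusion = inclusion, steps = prepared,
      events = events, segmentation = segmentation, trace = trace,
      event_table = event_table, models = models,
      detect_params = detect_params, complexity_pars = complexity_pars
    ),
    class = "stepdyn_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @noRd
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$summary, file.path(out_dir, "cohort_summary.csv"))
  readr::write_csv(result$inclusion, file.path(out_dir, "inclusion_report.csv"))
  readr::write_csv(as_tibble(result$events), file.path(out_dir, "events.csv"))
  readr::write_csv(result$segmentation, file.path(out_dir, "segmentation.csv"))
  readr::write_csv(result$trace, file.path(out_dir, "complexity_trace.csv"))
  fits <- purrr::compact(result$models)
  if (length(fits) > 0 && requireNamespace("jsonlite", quietly = TRUE)) {
    report <- purrr::map(fits, function(m) {
      list(
        n_participants = m$n_participants, n_records = m$n_records,
        n_events = m$n_events, converged = m$converged,
        odds_ratios = compute_odds_ratios(m)
      )
    })
    jsonlite::write_json(report, file.path(out_dir, "model_report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(result)
}

#' @export
print.stepdyn_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<stepdyn_pipeline> %d participants, %d events (%d gains / %d losses)\n",
    s$n_participants, s$n_events, s$n_gains, s$n_losses
  ))
  cat(sprintf(
    "  mean length %.0f d, mean daily steps %.0f, mean |delta| %.0f steps, mean gap %.1f d\n",
    s$mean_length_days, s$mean_daily_steps,
    s$mean_abs_delta_steps, s$mean_interevent_gap_days
  ))
  for (oc in names(x$models)) {
    if (!is.null(x$models[[oc]])) {
      ors <- compute_odds_ratios(x$models[[oc]])
      ldc <- ors[ors$term == "ldc", ]
      cat(sprintf(
        "  model %-6s LDC OR = %.3f [%.3f, %.3f]\n",
        oc, ldc$or, ldc$conf.low, ldc$conf.high
      ))
    }
  }
  invisible(x)
}

#' Run the sensitivity grid over thresholds, LDC lags and outcomes
#'
#' Re-runs detection and modelling over the full grid of gain/loss thresholds
#' and LDC lags, for each outcome framing. The segmentation does not depend on
#' the threshold and the complexity trace does not depend on the lag, so both
#' are computed once and reused; event counts do not depend on the lag.
#' Per-cell model failures are recorded in the cell and the grid completes.
#'
#' @param prepared Imputed person-day tibble (from [prepare_steps()]).
#' @param thresholds Fractions of the median (default `c(0.20, 0.30, 0.40)`).
#' @param lags LDC lags in days (default `2:4`).
#' @param outcomes Outcome framings (default all three).
#' @param detect_params Base [detection_params()] (its threshold is replaced
#'   per grid cell).
#' @param complexity_pars Base [complexity_params()] (its lag is replaced per
#'   grid cell).
#' @return Tibble with one row per (threshold, lag, outcome): `n_events`,
#'   `n_gains`, `n_losses`, `n_participants`, `or_ldc`, `conf.low`,
#'   `conf.high`, `converged`, `note`.
#' @export
run_sensitivity_grid <- function(prepared,
                                 thresholds = c(0.20, 0.30, 0.40),
                                 lags = 2:4,
                                 outcomes = c("both", "gains", "losses"),
                                 detect_params = detection_params(),
                                 complexity_pars = complexity_params()) {
  check_columns(prepared, c("participant_id", "day", "steps"), "prepared data")

  # detection per threshold (segmentation inside detect_transitions is
  # threshold-independent, classification is cheap)
  events_by_thr <- purrr::map(thresholds, function(thr) {
    p <- detect_params
    p$threshold_frac <- thr
    detect_transitions(prepared, p)
  })
  names(events_by_thr) <- as.character(thresholds)

  traces_by_lag <- purrr::map(lags, function(lg) {
    p <- complexity_pars
    p$ldc_lag_days <- as.integer(lg)
    complexity_trace(prepared, p)
  })
  names(traces_by_lag) <- as.character(lags)

  grid <- tidyr::expand_grid(
    threshold = thresholds, lag = lags, outcome = outcomes
  )
  rows <- purrr::pmap(grid, function(threshold, lag, outcome) {
    ev <- events_by_thr[[as.character(threshold)]]
    out <- tibble(
      threshold = threshold, lag = lag, outcome = outcome,
      n_events = nrow(ev),
      n_gains = sum(ev$direction == "gain"),
      n_losses = sum(ev$direction == "loss"),
      n_participants = NA_integer_, or_ldc = NA_real_,
      conf.low = NA_real_, conf.high = NA_real_,
      converged = NA, note = ""
    )
    fit <- tryCatch(
      {
        tab <- build_event_table(traces_by_lag[[as.character(lag)]], ev)
        fit_event_model(tab, outcome = outcome)
      },
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      out$note <- fit
    } else {
      ors <- compute_odds_ratios(fit)
      ldc <- ors[ors$term == "ldc", ]
      out$n_participants <- fit$n_participants
      out$or_ldc <- ldc$or
      out$conf.low <- ldc$conf.low
      out$conf.high <- ldc$conf.high
      out$converged <- fit$converged
    }
    out
  })
  bind_rows(rows)
}
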