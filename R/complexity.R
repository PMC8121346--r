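#' Parameters for dynamic-complexity computation
#'
#' @param window_days Length of the backward moving window in days (default
#'   7). The complexity score for day `n` is computed from the `window_days`
#'   daily values ending at `n` (days `n - window_days + 1` through `n`).
#' @param ldc_lag_days Lag of the local-dynamic-complexity predictor: the LDC
#'   for day `n` is the maximum complexity over the `ldc_lag_days` days
#'   strictly preceding `n` (default 3; sensitivity lags 2 and 4).
#' @param scale One of `"participant"` (default: scale bounds are the observed
#'   min/max of each participant's full imputed series, matching the
#'   idiographic anchoring of the distribution measure) or `"fixed"` with
#'   explicit `scale_min`/`scale_max`.
#' @param scale_min,scale_max Explicit scale bounds when `scale = "fixed"`.
#' @return An object of class `complexity_params`.
#' @export
complexity_params <- function(window_days = 7L, ldc_lag_days = 3L,
                              scale = c("participant", "fixed"),
                              scale_min = NULL, scale_max = NULL) {
  scale <- match.arg(scale)
  stopifnot(window_days >= 2, ldc_lag_days >= 1)
  if (scale == "fixed") {
    stopifnot(!is.null(scale_min), !is.null(scale_max), scale_max > scale_min)
  }
  structure(
    list(
      window_days = as.integer(window_days),
      ldc_lag_days = as.integer(ldc_lag_days),
      scale = scale, scale_min = scale_min, scale_max = scale_max
    ),
    class = "complexity_params"
  )
}

#' @noRd
clip_to_scale <- function(window, scale_min, scale_max) {
  if (any(window < scale_min | window > scale_max)) {
    warning("window values outside the scale bounds were clipped", call. = FALSE)
    window <- pmin(pmax(window, scale_min), scale_max)
  }
  window
}

#' Fluctuation intensity of a window
#'
#' `F` measures the amplitude and frequency of change within a window. The
#' window is partitioned into maximal monotone runs delimited by direction
#' reversals; a zero first-difference terminates a run (ties are not part of a
#' trend). A run spanning amplitude `a` over `d` day-intervals contributes
#' `a / d`; the sum is normalized by `s * (m - 1)` where `s` is the scale
#' range and `m` the window length. `F` is 0 for a constant window and 1 when
#' the values alternate between the scale extremes every day.
#'
#' @param window Numeric vector of `m` daily values.
#' @param scale_min,scale_max Scale bounds (values outside are clipped with a
#'   warning). A degenerate scale (`scale_max <= scale_min`) yields 0 by
#'   convention.
#' @return `F` in `[0, 1]`.
#' @export
#' @examples
#' fluctuation_intensity(rep(5, 7), 0, 10) # 0
#' fluctuation_intensity(rep(c(0, 10), length.out = 7), 0, 10) # 1
fluctuation_intensity <- function(window, scale_min, scale_max) {
  m <- length(window)
  stopifnot(m >= 2)
  s <- scale_max - scale_min
  if (s <= 0) {
    warning("degenerate scale range; F = 0 by convention", call. = FALSE)
    return(0)
  }
  w <- clip_to_scale(window, scale_min, scale_max)
  dw <- diff(w)
  sgn <- sign(dw)
  total <- 0
  i <- 1L
  while (i <= m - 1L) {
    if (sgn[i] == 0) { # a tie is its own zero-amplitude run
      i <- i + 1L
      next
    }
    j <- i
    while (j + 1L <= m - 1L && sgn[j + 1L] == sgn[i]) j <- j + 1L
    total <- total + abs(w[j + 1L] - w[i]) / (j - i + 1L)
    i <- j + 1L
  }
  total / (s * (m - 1))
}

#' Distribution measure of a window
#'
#' `D` measures how evenly the window's values cover the attainable scale
#' range. The sorted values are compared, over every index span, against the
#' spread of an ideal uniform grid over `[scale_min, scale_max]`; only
#' shortfalls (empirical spread below the uniform spread) accumulate.
#' `D = 1 - total shortfall / total uniform spread`: 0 for a constant window,
#' 1 for values exactly uniformly spaced across the full scale.
#'
#' @inheritParams fluctuation_intensity
#' @return `D` in `[0, 1]`.
#' @export
#' @examples
#' distribution_measure(seq(0, 10, length.out = 7), 0, 10) # 1
#' distribution_measure(rep(4, 7), 0, 10) # 0
distribution_measure <- function(window, scale_min, scale_max) {
  m <- length(window)
  stopifnot(m >= 2)
  s <- scale_max - scale_min
  if (s <= 0) {
    warning("degenerate scale range; D = 0 by convention", call. = FALSE)
    return(0)
  }
  y <- sort(clip_to_scale(window, scale_min, scale_max))
  u <- s / (m - 1)
  total_short <- 0
  total_unif <- 0
  for (c in seq_len(m - 1)) {
    emp <- y[(1 + c):m] - y[seq_len(m - c)]
    unif <- c * u
    total_unif <- total_unif + unif * (m - c)
    total_short <- total_short + sum(pmax(unif - emp, 0))
  }
  1 - total_short / total_unif
}

#' Per-day dynamic complexity trace of a cohort
#'
#' Computes, for every participant and every day `n` with a full backward
#' window, the fluctuation intensity `F`, the distribution measure `D`, their
#' product `C = F x D`, and the local dynamic complexity `ldc` (the maximum
#' `C` over the `ldc_lag_days` days strictly preceding `n`). Days before the
#' first full window (or without enough complexity history for the LDC) are
#' `NA`, not zero.
#'
#' @param data Imputed long person-day tibble with `participant_id`, `day`,
#'   `steps`.
#' @param params A [complexity_params()]. With the default
#'   `scale = "participant"`, the scale bounds are each participant's observed
#'   min/max over the full imputed series.
#' @return `data` with added columns `F`, `D`, `C`, `ldc`.
#' @export
#' @examples
#' d <- tibble::tibble(participant_id = "P1", day = 1:30,
#'                     steps = 8000 + 500 * sin(1:30))
#' tr <- complexity_trace(d)
#' range(tr$C, na.rm = TRUE)
complexity_trace <- function(data, params = complexity_params()) {
  check_columns(data, c("participant_id", "day", "steps"), "prepared data")
  if (any(is.na(data$steps))) {
    stop_stepdyn("complexity_trace() requires a complete (imputed) series")
  }
  m <- params$window_days
  lag_d <- params$ldc_lag_days
  data %>%
    arrange(.data$participant_id, .data$day) %>%
    group_by(.data$participant_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      n <- nrow(d)
      if (n < m) {
        stop_stepdyn(sprintf(
          "series for %s (%d days) is shorter than the %d-day window",
          d$participant_id[1], n, m
        ))
      }
      if (params$scale == "participant") {
        smin <- min(d$steps)
        smax <- max(d$steps)
      } else {
        smin <- params$scale_min
        smax <- params$scale_max
      }
      Fv <- rep(NA_real_, n)
      Dv <- rep(NA_real_, n)
      for (i in m:n) {
        win <- d$steps[(i - m + 1):i]
        Fv[i] <- fluctuation_intensity(win, smin, smax)
        Dv[i] <- distribution_measure(win, smin, smax)
      }
      Cv <- Fv * Dv
      ldc <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        if (i - lag_d >= m) ldc[i] <- max(Cv[(i - lag_d):(i - 1)])
      }
      d$F <- Fv
      d$D <- Dv
      d$C <- Cv
      d$ldc <- ldc
      d
    }) %>%
    bind_rows()
}

#' Local dynamic complexity for one day
#'
#' The early-warning predictor: the maximum dynamic complexity `C` over the
#' `lag` days strictly preceding `day` (the day itself is excluded). Undefined
#' (`NA`) when any of those days lacks a complexity value; such days are
#' excluded downstream.
#'
#' @param trace Trace tibble from [complexity_trace()] for a single
#'   participant (or filtered to one).
#' @param day Study day index.
#' @param lag Number of preceding days (default from `params`).
#' @param params A [complexity_params()].
#' @return LDC value in `[0, 1]`, or `NA` if history is insufficient.
#' @export
local_dynamic_complexity <- function(trace, day, lag = NULL,
                                     params = complexity_params()) {
  check_columns(trace, c("day", "C"), "complexity trace")
  lag <- lag %||% params$ldc_lag_days
  idx <- match((day - lag):(day - 1), trace$day)
  if (any(is.na(idx))) {
    return(NA_real_)
  }
  vals <- trace$C[idx]
  if (any(is.na(vals))) {
    return(NA_real_)
  }
  max(vals)
}
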