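#' Parameters for sudden gain/loss detection
#'
#' @param threshold_frac Fraction of the participant's study-period median
#'   step count that a level shift must reach to qualify as a sudden gain or
#'   loss (default 0.30; sensitivity values 0.20 and 0.40).
#' @param min_segment_days Minimum stable-regime duration in days (default 7):
#'   both flanking segments of a shift must persist at least this long. This
#'   also structurally controls for weekday/weekend level differences, since a
#'   qualifying regime always spans a full week.
#' @param complexity_parameter Minimum relative reduction of the root
#'   sum-of-squares required to accept a split (default 0.01, the canonical
#'   CART default).
#' @param max_depth Maximum recursion depth of the partitioning (default 30).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_frac = 0.30, min_segment_days = 7L,
                             complexity_parameter = 0.01, max_depth = 30L) {
  stopifnot(
    threshold_frac > 0, min_segment_days >= 1,
    complexity_parameter >= 0, max_depth >= 1
  )
  structure(
    list(
      threshold_frac = threshold_frac,
      min_segment_days = as.integer(min_segment_days),
      complexity_parameter = complexity_parameter,
      max_depth = as.integer(max_depth)
    ),
    class = "detection_params"
  )
}

#' Segment one step series by recursive partitioning on the day index
#'
#' CART-style recursive binary splitting of the daily step sequence with the
#' study day as the only predictor. At each node the split day minimizing the
#' total within-child sum of squared errors is chosen (earliest day on ties);
#' a split is accepted only if both children span at least
#' `min_segment_days` days and the SSE reduction is at least
#' `complexity_parameter` times the root SSE. The result is a piecewise-
#' constant fit whose segment levels are the segment means.
#'
#' @param steps Complete (imputed) numeric vector of daily step counts.
#' @param params A [detection_params()].
#' @return Tibble with one row per segment: `segment`, `start`, `end`
#'   (inclusive day indices, 1-based), `length`, `level` (segment mean).
#'   Breakpoints — the first day of each new segment — are
#'   `start[-1]`.
#' @export
#' @examples
#' y <- c(rep(6000, 50), rep(9000, 50))
#' segment_series(y, detection_params())
segment_series <- function(steps, params = detection_params()) {
  stopifnot(is.numeric(steps), all(is.finite(steps)))
  n <- length(steps)
  ms <- params$min_segment_days
  if (n < 2 * ms) {
    warning(sprintf(
      "series of %d days is shorter than 2 x min_segment_days; returning a single segment",
      n
    ), call. = FALSE)
    return(tibble(
      segment = 1L, start = 1L, end = n, length = n, level = mean(steps)
    ))
  }

  cs <- cumsum(steps)
  cs2 <- cumsum(steps^2)
  sse <- function(a, b) {
    s <- cs[b] - if (a > 1) cs[a - 1] else 0
    s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    max(s2 - s^2 / (b - a + 1), 0)
  }
  root_sse <- sse(1, n)
  min_gain <- params$complexity_parameter * root_sse

  recurse <- function(a, b, depth) {
    if (b - a + 1 < 2 * ms || depth >= params$max_depth) {
      return(integer(0))
    }
    ts <- seq(a + ms, b - ms + 1)             # split day = first day of right child
    node_sse <- sse(a, b)
    best_t <- NA_integer_
    best_child <- Inf
    for (t in ts) {                            # earliest day wins ties (strict <)
      child <- sse(a, t - 1) + sse(t, b)
      if (child < best_child) {
        best_child <- child
        best_t <- t
      }
    }
    improvement <- node_sse - best_child
    if (!(improvement > 0 && improvement >= min_gain)) {
      return(integer(0))
    }
    c(
      recurse(a, best_t - 1L, depth + 1L),
      best_t,
      recurse(best_t, b, depth + 1L)
    )
  }
  bps <- sort(recurse(1L, n, 0L))
  starts <- c(1L, bps)
  ends <- c(bps - 1L, n)
  tibble(
    segment = seq_along(starts),
    start = as.integer(starts),
    end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    level = purrr::map2_dbl(starts, ends, ~ mean(steps[.x:.y]))
  )
}

#' Step-count cut corresponding to a fraction-of-median criterion
#'
#' The absolute level change (steps/day) that a shift must reach to qualify as
#' a sudden gain or loss for a participant with the given median.
#'
#' @param participant_median Median daily steps over the participant's study
#'   period.
#' @param threshold_frac Fraction of the median (default 0.30).
#' @return The cut in steps/day (e.g. 2100 for a median of 7000 at 30%).
#' @export
threshold_cut <- function(participant_median, threshold_frac = 0.30) {
  stopifnot(participant_median >= 0, threshold_frac > 0)
  threshold_frac * participant_median
}

#' Classify segment-to-segment shifts as sudden gains or losses
#'
#' For each adjacent pair of segments, a transition event is emitted when the
#' absolute level difference reaches `threshold_frac` times the participant's
#' study-period median. Both flanking segments already satisfy the
#' `min_segment_days` stability criterion by construction of the
#' segmentation. Sub-threshold splits produce no event.
#'
#' @param segmentation Segment tibble from [segment_series()].
#' @param participant_median Median daily steps over the full imputed study
#'   period (the median, not the mean, to manage right-skewed step
#'   distributions).
#' @param params A [detection_params()].
#' @return Tibble with one row per event: `day` (first day of the new
#'   regime), `direction` (`"gain"`/`"loss"`), `pre_level`, `post_level`,
#'   `delta_steps`, `delta_frac` (relative to the participant median).
#' @export
#' @examples
#' seg <- segment_series(c(rep(7000, 30), rep(9200, 30)))
#' classify_transitions(seg, participant_median = 7000)
classify_transitions <- function(segmentation, participant_median,
                                 params = detection_params()) {
  if (any(!is.finite(segmentation$level))) {
    stop_stepdyn("non-finite segment level")
  }
  if (nrow(segmentation) < 2) {
    return(tibble(
      day = integer(0), direction = character(0), pre_level = numeric(0),
      post_level = numeric(0), delta_steps = numeric(0), delta_frac = numeric(0)
    ))
  }
  cut <- threshold_cut(participant_median, params$threshold_frac)
  pre <- head(segmentation$level, -1)
  post <- tail(segmentation$level, -1)
  delta <- post - pre
  keep <- abs(delta) >= cut
  tibble(
    day = tail(segmentation$start, -1)[keep],
    direction = if_else(delta[keep] > 0, "gain", "loss"),
    pre_level = pre[keep],
    post_level = post[keep],
    delta_steps = delta[keep],
    delta_frac = delta[keep] / participant_median
  )
}

#' Detect sudden gains and losses across a prepared cohort
#'
#' Runs [segment_series()] and [classify_transitions()] per participant on an
#' imputed person-day tibble. The participant median is computed internally
#' over the full imputed study period.
#'
#' @param data Imputed long person-day tibble with `participant_id`, `day`,
#'   `steps` (no missing values; see [prepare_steps()]).
#' @param params A [detection_params()].
#' @return Tibble of transition events with `participant_id`, `day`, `date`
#'   (if present in `data`), `direction`, `pre_level`, `post_level`,
#'   `delta_steps`, `delta_frac`. The per-participant segmentations are
#'   attached as attribute `"segmentation"` (a tibble with `participant_id`
#'   and the [segment_series()] columns).
#' @export
detect_transitions <- function(data, params = detection_params()) {
  check_columns(data, c("participant_id", "day", "steps"), "prepared data")
  if (any(is.na(data$steps))) {
    stop_stepdyn("detect_transitions() requires a complete (imputed) series")
  }
  parts <- data %>%
    arrange(.data$participant_id, .data$day) %>%
    group_by(.data$participant_id) %>%
    group_split()
  seg_all <- list()
  ev_all <- list()
  for (d in parts) {
    seg <- segment_series(d$steps, params)
    ev <- classify_transitions(seg, median(d$steps), params)
    seg$participant_id <- d$participant_id[1]
    if (nrow(ev) > 0) {
      ev$participant_id <- d$participant_id[1]
      if ("date" %in% names(d)) ev$date <- d$date[match(ev$day, d$day)]
    }
    seg_all[[length(seg_all) + 1]] <- seg
    ev_all[[length(ev_all) + 1]] <- ev
  }
  events <- bind_rows(ev_all)
  if (nrow(events) == 0) {
    events <- tibble(
      participant_id = character(0), day = integer(0), direction = character(0),
      pre_level = numeric(0), post_level = numeric(0),
      delta_steps = numeric(0), delta_frac = numeric(0)
    )
  } else {
    front <- c("participant_id", if ("date" %in% names(events)) "date", "day")
    events <- events %>% select(all_of(front), dplyr::everything())
  }
  attr(events, "segmentation") <- bind_rows(seg_all) %>%
    select(all_of(c("participant_id", "segment", "start", "end", "length", "level")))
  events
}
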