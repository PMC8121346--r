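#' Plot daily step series with detected transitions
#'
#' Line plot of daily steps per participant, with vertical markers at detected
#' sudden gains (upward shifts) and losses (downward shifts) and the fitted
#' piecewise-constant segmentation overlaid when available.
#'
#' @param data Person-day tibble with `participant_id`, `day`, `steps`.
#' @param events Optional event tibble from [detect_transitions()]; its
#'   `"segmentation"` attribute is drawn when present.
#' @param participants Optional character vector restricting the facets.
#' @return A ggplot object.
#' @export
plot_step_series <- function(data, events = NULL, participants = NULL) {
  check_columns(data, c("participant_id", "day", "steps"), "series data")
  if (!is.null(participants)) {
    data <- data %>% filter(.data$participant_id %in% participants)
    if (!is.null(events)) {
      seg <- attr(events, "segmentation")
      events <- events %>% filter(.data$participant_id %in% participants)
      attr(events, "segmentation") <- seg
    }
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$day, y = .data$steps)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::facet_wrap(~participant_id, scales = "free") +
    ggplot2::labs(x = "study day", y = "daily steps") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    seg <- attr(events, "segmentation")
    if (!is.null(seg)) {
      if (!is.null(participants)) {
        seg <- seg %>% filter(.data$participant_id %in% participants)
      }
      p <- p + ggplot2::geom_segment(
        data = seg,
        ggplot2::aes(
          x = .data$start, xend = .data$end,
          y = .data$level, yend = .data$level
        ),
        colour = "steelblue", linewidth = 0.8
      )
    }
    if (nrow(events) > 0) {
      p <- p + ggplot2::geom_vline(
        data = events,
        ggplot2::aes(xintercept = .data$day, colour = .data$direction),
        linetype = "dashed"
      ) +
        ggplot2::scale_colour_manual(
          values = c(gain = "forestgreen", loss = "firebrick"),
          name = "transition"
        )
    }
  }
  p
}

#' Plot a dynamic-complexity trace beneath the step series
#'
#' Two stacked panels per participant: the daily step series and the per-day
#' dynamic complexity `C = F x D`, so that pre-transition complexity peaks
#' (the early-warning signature) are visible.
#'
#' @param trace Trace tibble from [complexity_trace()].
#' @param participants Optional character vector restricting the facets.
#' @return A ggplot object.
#' @export
plot_complexity_trace <- function(trace, participants = NULL) {
  check_columns(trace, c("participant_id", "day", "steps", "C"), "complexity trace")
  if (!is.null(participants)) {
    trace <- trace %>% filter(.data$participant_id %in% participants)
  }
  long <- trace %>%
    select(all_of(c("participant_id", "day", "steps", "C"))) %>%
    tidyr::pivot_longer(c("steps", "C"), names_to = "panel", values_to = "value") %>%
    mutate(panel = factor(.data$panel,
      levels = c("steps", "C"),
      labels = c("daily steps", "dynamic complexity (F x D)")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30", na.rm = TRUE) +
    ggplot2::facet_grid(panel ~ participant_id, scales = "free_y") +
    ggplot2::labs(x = "study day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot method for pipeline results
#'
#' Shows up to `n_participants` series with their detected transitions.
#'
#' @param object A `stepdyn_pipeline` from [run_pipeline()].
#' @param n_participants Number of participants to display (default 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot stepdyn_pipeline
#' @export
autoplot.stepdyn_pipeline <- function(object, n_participants = 6, ...) {
  ids <- head(unique(object$steps$participant_id), n_participants)
  plot_step_series(object$steps, object$events, participants = ids)
}

#' @export
ggplot2::autoplot
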