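#' Simulate one participant's daily step series with known ground truth
#'
#' Draws a piecewise-stable daily step-count series: regime levels alternate
#' above/below the participant's base level, transitions are instantaneous
#' level shifts, each day's count is `level x weekend factor x noise`, rounded
#' to a non-negative integer. The `precursor_window` days before each
#' transition have their noise SD multiplied by the direction-specific
#' precursor multiplier, planting an early-warning signature.
#'
#' @param config A [cohort_config()].
#' @param participant_id Identifier string for the output tibble.
#' @param participant_seed Integer seed; the series is a deterministic
#'   function of `config` and this seed.
#' @param force Optional list overriding the random regime structure, with
#'   elements `breakpoints` (day indices of the first day of each new regime),
#'   `directions` (`"gain"`/`"loss"` per breakpoint), `magnitudes` (fractional
#'   shift per breakpoint) and optionally `length` and `base_level`. Used to
#'   inject exactly known transitions.
#'
#' @return A list with elements
#'   * `steps`: tibble with `participant_id`, `date`, `day`, `steps`
#'     (complete, no missing days), `weekend`;
#'   * `truth`: tibble with `participant_id`, `breakpoint_day`, `direction`,
#'     `pre_level`, `post_level` (zero rows if no transitions);
#'   * `precursors`: tibble with `participant_id`, `day` of each
#'     variance-inflated precursor day.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 7)
#' sim <- simulate_series(cfg, "P001", participant_seed = 7)
#' nrow(sim$truth)
simulate_series <- function(config, participant_id = "P001",
                            participant_seed = config$seed, force = NULL) {
  validate_cohort_config(config)
  withr::with_seed(participant_seed, {
    simulate_series_impl(config, participant_id, force)
  })
}

#' @noRd
simulate_series_impl <- function(config, participant_id, force = NULL) {
  sl <- config$series_length
  n <- if (!is.null(force$length)) {
    as.integer(force$length)
  } else {
    as.integer(round(min(max(rnorm(1, sl$mean, sl$sd %||% 0), sl$min), sl$max)))
  }
  base <- if (!is.null(force$base_level)) {
    force$base_level
  } else {
    max(config$base_level$min %||% 1, rnorm(1, config$base_level$mean, config$base_level$sd %||% 0))
  }

  if (!is.null(force$breakpoints)) {
    bps <- as.integer(force$breakpoints)
    stopifnot(all(bps > 1), all(bps <= n), !is.unsorted(bps, strictly = TRUE))
    dirs <- force$directions
    mags <- force$magnitudes %||% rep(mean(config$transition_magnitude), length(bps))
    levels <- numeric(length(bps) + 1)
    levels[1] <- base
    for (j in seq_along(bps)) {
      sgn <- if (dirs[j] == "gain") 1 else -1
      levels[j + 1] <- levels[j] * (1 + sgn * mags[j])
    }
  } else if (config$regime_change_rate <= 0) {
    bps <- integer(0)
    levels <- base
    dirs <- character(0)
  } else {
    mean_gap <- 30 / config$regime_change_rate
    extra_mean <- max(mean_gap - config$min_regime_length, 0.5)
    p_geom <- 1 / (1 + extra_mean)
    lens <- integer(0)
    while (sum(lens) < n) {
      lens <- c(lens, config$min_regime_length + rgeom(1, p_geom))
    }
    cum <- cumsum(lens)
    lens <- lens[seq_len(which(cum >= n)[1])]
    lens[length(lens)] <- n - sum(head(lens, -1))
    # a truncated short tail regime is merged into its predecessor
    if (length(lens) > 1 && lens[length(lens)] < config$min_regime_length) {
      lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
      lens <- head(lens, -1)
    }
    n_regimes <- length(lens)
    bps <- if (n_regimes > 1) cumsum(head(lens, -1)) + 1L else integer(0)
    # regime levels alternate above/below the base level
    sgn0 <- sample(c(-1, 1), 1)
    sgn <- sgn0 * (-1)^(seq_len(n_regimes) - 1)
    mag <- runif(n_regimes, config$transition_magnitude[1], config$transition_magnitude[2])
    levels <- base * (1 + sgn * mag)
    dirs <- ifelse(diff(levels) > 0, "gain", "loss")
  }

  regime_of_day <- findInterval(seq_len(n), c(1L, bps))
  level_day <- levels[regime_of_day]

  # precursor days: the window immediately before each breakpoint, clipped to
  # the current regime
  sd_mult <- rep(1, n)
  precursor_days <- integer(0)
  if (length(bps) > 0 && config$precursor_window > 0) {
    reg_start <- c(1L, bps)
    for (j in seq_along(bps)) {
      d0 <- max(reg_start[j], bps[j] - config$precursor_window)
      days_j <- seq(d0, bps[j] - 1L)
      mult <- if (dirs[j] == "loss") {
        config$precursor_sd_multiplier_loss
      } else {
        config$precursor_sd_multiplier_gain
      }
      sd_mult[days_j] <- pmax(sd_mult[days_j], mult)
      if (mult > 1) precursor_days <- c(precursor_days, days_j)
    }
  }

  dates <- config$start_date + seq_len(n) - 1L
  wkend <- is_weekend(dates)
  mu <- level_day * ifelse(wkend, config$weekend_factor, 1)

  if (config$noise_model == "lognormal") {
    sig <- config$noise_sigma * sd_mult
    z <- rnorm(n)
    if (config$ar1 > 0) {
      phi <- config$ar1
      z <- as.numeric(stats::filter(z * sqrt(1 - phi^2), phi, method = "recursive"))
      z[1] <- z[1] / sqrt(1 - phi^2) # restore unit marginal sd at t = 1
    }
    eps <- exp(sig * z - sig^2 / 2) # mean-one multiplicative noise
    steps <- pmax(0, round(mu * eps))
  } else {
    size <- config$nb_dispersion
    # inflate the variance on precursor days by the squared sd multiplier
    var0 <- mu + mu^2 / size
    var_d <- sd_mult^2 * var0
    size_d <- ifelse(var_d > mu, mu^2 / (var_d - mu), Inf)
    steps <- ifelse(
      is.finite(size_d),
      rnbinom(n, mu = mu, size = size_d),
      stats::rpois(n, mu)
    )
  }

  steps_tbl <- tibble(
    participant_id = participant_id,
    date = dates,
    day = seq_len(n),
    steps = as.numeric(steps),
    weekend = wkend
  )
  truth <- tibble(
    participant_id = rep(participant_id, length(bps)),
    breakpoint_day = as.integer(bps),
    direction = as.character(dirs),
    pre_level = levels[seq_along(bps)],
    post_level = levels[seq_along(bps) + 1]
  )
  precursors <- tibble(
    participant_id = rep(participant_id, length(precursor_days)),
    day = as.integer(sort(unique(precursor_days)))
  )
  list(steps = steps_tbl, truth = truth, precursors = precursors)
}

#' Simulate a cohort of participants with ground truth and missingness
#'
#' Generates `config$n_participants` independent series via
#' [simulate_series()], using per-participant seeds derived reproducibly from
#' `config$seed`, then injects missing days per [inject_missingness()] with a
#' per-participant missing fraction drawn from `config$missing_frac`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `stepdyn_cohort`: a list with tibbles `steps`
#'   (long person-day format; `steps` is `NA` on missing days and the
#'   pre-masking value is kept in `true_steps`), `truth`, `precursors`, and
#'   the `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 3, seed = 11))
#' dplyr::count(coh$steps, participant_id)
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  ids <- sprintf("P%03d", seq_len(config$n_participants))
  sims <- purrr::map(seq_len(config$n_participants), function(i) {
    ps <- participant_seed(config$seed, i)
    sim <- simulate_series(config, ids[i], participant_seed = ps)
    # per-participant missing fraction, truncated normal on [0, max]
    frac <- withr::with_seed(participant_seed(config$seed, i + config$n_participants), {
      min(max(rnorm(1, config$missing_frac$mean, config$missing_frac$sd %||% 0), 0),
          config$missing_frac$max)
    })
    sim$steps <- inject_missingness(
      sim$steps,
      frac = frac,
      gap_mean = config$missing_gap_mean,
      seed = participant_seed(config$seed, i + 2L * config$n_participants)
    )
    sim
  })
  structure(
    list(
      steps = bind_rows(purrr::map(sims, "steps")),
      truth = bind_rows(purrr::map(sims, "truth")),
      precursors = bind_rows(purrr::map(sims, "precursors")),
      config = config
    ),
    class = "stepdyn_cohort"
  )
}

#' @export
print.stepdyn_cohort <- function(x, ...) {
  np <- n_distinct(x$steps$participant_id)
  cat(sprintf(
    "<stepdyn_cohort> %d participants, %d person-days, %d true transitions\n",
    np, nrow(x$steps), nrow(x$truth)
  ))
  invisible(x)
}

#' Mask days of a complete series as missing, preserving the truth
#'
#' Randomly selects days to set to `NA`, using geometric run lengths to mimic
#' the multi-day gap structure of device non-wear. The pre-masking values are
#' retained in a `true_steps` column so imputation can be scored against them.
#'
#' @param data Tibble with at least `participant_id`, `day`, `steps`
#'   (complete; from [simulate_series()]).
#' @param frac Fraction of days to mask, in `[0, 1)`. With `exact = TRUE`
#'   (default) exactly `round(frac * n)` days are masked per participant.
#' @param gap_mean Mean geometric run length of a missing gap, in days.
#' @param exact Mask exactly `round(frac * n)` days (default) rather than a
#'   random number.
#' @param seed Optional integer seed for reproducibility.
#' @return The input tibble with masked `steps` and a `true_steps` column.
#' @export
#' @examples
#' sim <- simulate_series(cohort_config(seed = 1), "P001")
#' masked <- inject_missingness(sim$steps, frac = 0.1, seed = 2)
#' mean(is.na(masked$steps))
inject_missingness <- function(data, frac, gap_mean = 2, exact = TRUE, seed = NULL) {
  check_columns(data, c("participant_id", "day", "steps"), "series data")
  if (frac >= 1) stop_stepdyn("missing fraction must be < 1")
  if (!("true_steps" %in% names(data))) data$true_steps <- data$steps
  if (frac <= 0) {
    return(data)
  }
  run <- function() {
    data %>%
      group_by(.data$participant_id) %>%
      group_split() %>%
      purrr::map(function(d) {
        n <- nrow(d)
        target <- if (exact) round(frac * n) else sum(runif(n) < frac)
        if (target == 0) {
          return(d)
        }
        miss <- rep(FALSE, n)
        guard <- 0
        while (sum(miss) < target && guard < 50 * n) {
          guard <- guard + 1
          len <- min(1 + rgeom(1, 1 / gap_mean), target - sum(miss))
          start <- sample.int(n - len + 1, 1)
          idx <- start:(start + len - 1)
          if (!any(miss[idx])) miss[idx] <- TRUE
        }
        d$steps[miss] <- NA_real_
        d
      }) %>%
      bind_rows()
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
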