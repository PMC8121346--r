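#' Configuration for the synthetic step-count cohort generator
#'
#' Defines the statistical structure of a simulated cohort of daily
#' step-count series with known ground truth: piecewise-stable regimes joined
#' by instantaneous level shifts (sudden gains/losses), weekday/weekend level
#' differences, multiplicative daily noise, optional pre-transition variance
#' inflation (the early-warning precursor), and missing days with a gap-run
#' structure.
#'
#' The defaults emulate a long wearable accelerometry study of ~151 adults:
#' series of mean length 226 days (range 107-320), cohort mean around 9700
#' steps/day, roughly 6 level transitions per participant with mean magnitude
#' near 4900 steps and mean inter-event spacing near 31 days, and a mean of
#' about 20 missing days per participant (at most ~27% of a series).
#'
#' @param n_participants Number of participants to simulate.
#' @param series_length List with `mean`, `sd`, `min`, `max` (days); lengths
#'   are drawn from a normal distribution and clamped to `[min, max]`.
#' @param base_level List with `mean`, `sd`, `min` (steps/day); each
#'   participant's central step level. The default mean is chosen so that the
#'   cohort mean daily count (after the weekend factor) lands near 9687.
#' @param regime_change_rate Expected number of level transitions per 30 days
#'   of observation. `0` disables transitions entirely.
#' @param transition_magnitude Length-2 numeric: uniform range of the
#'   fractional offset of each regime level from the participant base level.
#'   Consecutive regimes alternate above/below the base, so consecutive levels
#'   differ by the sum of two draws (default mean shift ~0.48 of base).
#' @param min_regime_length Minimum regime duration in days (>= 1).
#' @param weekend_factor Multiplicative level factor applied on Saturdays and
#'   Sundays (default 0.85, a modest weekend dip).
#' @param noise_model `"lognormal"` (multiplicative, mean-one, right-skewed;
#'   the default, since daily step counts are right-skewed) or
#'   `"negative-binomial"` (count noise with dispersion `nb_dispersion`).
#' @param noise_sigma Log-scale standard deviation of the lognormal noise.
#' @param nb_dispersion Negative-binomial size parameter (larger = less noise).
#' @param ar1 Optional AR(1) coefficient of the within-regime noise process
#'   (default 0: independent days).
#' @param precursor_window Days of variance inflation immediately before each
#'   transition (the critical-fluctuation precursor).
#' @param precursor_sd_multiplier_loss,precursor_sd_multiplier_gain
#'   Multipliers applied to the noise SD on precursor days, by direction of
#'   the upcoming transition. The defaults (2 before losses, 1 before gains)
#'   encode the loss-specific early-warning structure the generator emulates.
#' @param missing_frac List with `mean`, `sd`, `max`: per-participant missing
#'   fraction is drawn from a normal distribution truncated to `[0, max]`.
#' @param missing_gap_mean Mean length (days) of a missing run; runs are
#'   geometric to mimic multi-day non-wear gaps.
#' @param start_date First calendar day of every simulated series.
#' @param seed Integer master seed; all per-participant randomness derives
#'   from it reproducibly.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_series()], [simulate_cohort()], [inject_missingness()]
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 5, seed = 42)
#' cfg$regime_change_rate
cohort_config <- function(n_participants = 151,
                          series_length = list(mean = 226, sd = 55, min = 107, max = 320),
                          base_level = list(mean = 10120, sd = 2200, min = 2500),
                          regime_change_rate = 0.95,
                          transition_magnitude = c(0.17, 0.31),
                          min_regime_length = 10,
                          weekend_factor = 0.85,
                          noise_model = c("lognormal", "negative-binomial"),
                          noise_sigma = 0.25,
                          nb_dispersion = 16,
                          ar1 = 0,
                          precursor_window = 5,
                          precursor_sd_multiplier_loss = 2,
                          precursor_sd_multiplier_gain = 1,
                          missing_frac = list(mean = 0.088, sd = 0.05, max = 0.27),
                          missing_gap_mean = 2,
                          start_date = as.Date("2019-06-03"),
                          seed = 1L) {
  noise_model <- match.arg(noise_model)

  cfg <- structure(
    list(
      n_participants = as.integer(n_participants),
      series_length = series_length,
      base_level = base_level,
      regime_change_rate = regime_change_rate,
      transition_magnitude = sort(transition_magnitude),
      min_regime_length = as.integer(min_regime_length),
      weekend_factor = weekend_factor,
      noise_model = noise_model,
      noise_sigma = noise_sigma,
      nb_dispersion = nb_dispersion,
      ar1 = ar1,
      precursor_window = as.integer(precursor_window),
      precursor_sd_multiplier_loss = precursor_sd_multiplier_loss,
      precursor_sd_multiplier_gain = precursor_sd_multiplier_gain,
      missing_frac = missing_frac,
      missing_gap_mean = missing_gap_mean,
      start_date = as.Date(start_date),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' @noRd
validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1,
    cfg$min_regime_length >= 1,
    cfg$regime_change_rate >= 0,
    cfg$noise_sigma >= 0,
    cfg$nb_dispersion > 0,
    cfg$precursor_window >= 0,
    cfg$precursor_sd_multiplier_loss > 0,
    cfg$precursor_sd_multiplier_gain > 0,
    cfg$ar1 >= 0, cfg$ar1 < 1,
    cfg$series_length$min >= 2,
    cfg$series_length$max >= cfg$series_length$min,
    cfg$base_level$mean > 0
  )
  fracs <- c(
    cfg$weekend_factor, cfg$transition_magnitude,
    cfg$missing_frac$mean, cfg$missing_frac$max
  )
  if (any(fracs < 0 | fracs > 1)) {
    stop_stepdyn("all fractional parameters must lie in [0, 1]",
      class = "stepdyn_config_error"
    )
  }
  if (cfg$regime_change_rate > 0) {
    expected_regimes <- cfg$series_length$mean * cfg$regime_change_rate / 30 + 1
    if (cfg$min_regime_length * expected_regimes > cfg$series_length$mean) {
      stop_stepdyn(paste0(
        "configuration error: min_regime_length x expected regimes (",
        round(cfg$min_regime_length * expected_regimes, 1),
        " days) exceeds the mean series length (",
        cfg$series_length$mean, " days)"
      ), class = "stepdyn_config_error")
    }
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  participants: %d, seed %d\n", x$n_participants, x$seed))
  cat(sprintf(
    "  series length: mean %s d [%s, %s]\n",
    x$series_length$mean, x$series_length$min, x$series_length$max
  ))
  cat(sprintf(
    "  base level: %s (sd %s) steps/day, weekend factor %.2f\n",
    x$base_level$mean, x$base_level$sd, x$weekend_factor
  ))
  cat(sprintf(
    "  transitions: %.2f per 30 d, magnitude U(%.2f, %.2f), min regime %d d\n",
    x$regime_change_rate, x$transition_magnitude[1],
    x$transition_magnitude[2], x$min_regime_length
  ))
  cat(sprintf(
    "  noise: %s (sigma %.2f, ar1 %.2f); precursor %d d, sd x%.1f (loss) / x%.1f (gain)\n",
    x$noise_model, x$noise_sigma, x$ar1, x$precursor_window,
    x$precursor_sd_multiplier_loss, x$precursor_sd_multiplier_gain
  ))
  cat(sprintf(
    "  missingness: mean frac %.3f (max %.2f), gap mean %.1f d\n",
    x$missing_frac$mean, x$missing_frac$max, x$missing_gap_mean
  ))
  invisible(x)
}
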