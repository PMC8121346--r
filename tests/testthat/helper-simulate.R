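# Builders for test fixtures, all generated in code under fixed seeds.

make_series_tbl <- function(steps, id = "P1") {
  tibble::tibble(
    participant_id = id,
    day = seq_along(steps),
    steps = as.numeric(steps)
  )
}

# Day-level event-history data simulated straight from the logistic GLMM:
# ldc is a smooth standardized process, the hazard is
# plogis(beta0 + b_i + beta_ldc * ldc), and the duration clock is recomputed
# from the realized events with the package's convention.
simulate_eh_data <- function(n_participants, n_days, beta_ldc = 0,
                             beta0 = -4, re_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_participants), function(i) {
      z <- as.numeric(stats::filter(rnorm(n_days), 0.5, method = "recursive"))
      ldc <- (z - mean(z)) / sd(z)
      b0 <- beta0 + rnorm(1, 0, re_sd)
      y <- rbinom(n_days, 1, plogis(b0 + beta_ldc * ldc))
      days <- seq_len(n_days)
      tibble::tibble(
        participant_id = sprintf("S%03d", i),
        day = days,
        time = days,
        duration = oracle_duration(days, days[y == 1]),
        ldc = ldc,
        gain = y, loss = y, event = y
      )
    })
  })
}

# A small cohort with calibrated (reduced) noise and no precursor inflation,
# for detection-recovery checks where the question is algorithmic correctness.
calibrated_cohort <- function(n = 25, seed = 1, noise_sigma = 0.10) {
  cohort_config(
    n_participants = n,
    noise_sigma = noise_sigma,
    precursor_sd_multiplier_loss = 1,
    precursor_sd_multiplier_gain = 1,
    seed = seed
  )
}
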