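# deterministic wiggly LDC so the predictor has variance
make_trace_stub <- function(id, n, warmup = 9) {
  day <- seq_len(n)
  tibble::tibble(
    participant_id = id, day = day,
    ldc = ifelse(day <= warmup, NA_real_, 0.15 + 0.1 * sin(day / 3))
  )
}

test_that("censored participants contribute all-zero rows with a rising clock", {
  trace <- make_trace_stub("P1", 109)
  events <- tibble::tibble(
    participant_id = character(0), day = integer(0), direction = character(0)
  )
  tab <- build_event_table(trace, events)
  expect_equal(nrow(tab), 100) # warm-up days excluded
  expect_true(all(tab$event == 0))
  expect_true(all(diff(tab$duration) == 1))
  expect_equal(tab$duration, tab$day) # no prior event: days since study start
})

test_that("the duration clock resets the day after each event", {
  trace <- make_trace_stub("P1", 80)
  events <- tibble::tibble(
    participant_id = "P1", day = c(30L, 60L), direction = c("gain", "loss")
  )
  tab <- build_event_table(trace, events)
  expect_equal(tab$duration[tab$day == 45], 15)
  expect_equal(tab$duration[tab$day == 61], 1)
  expect_equal(tab$duration[tab$day == 30], 30)
  expect_equal(sum(tab$event), 2)
  expect_equal(sum(tab$gain), 1)
  expect_equal(sum(tab$loss), 1)
  # independent single-pass recount
  expect_equal(tab$duration, oracle_duration(tab$day, c(30, 60)))
  expect_true(all(tab$duration >= 1))

  out_of_range <- tibble::tibble(
    participant_id = "P1", day = 999L, direction = "gain"
  )
  expect_error(build_event_table(trace, out_of_range), "outside")
})

test_that("event-table outcomes recount the events with defined LDC", {
  coh <- simulate_cohort(calibrated_cohort(n = 6, seed = 5))
  prep <- suppressMessages(suppressWarnings(prepare_steps(coh$steps)))
  ev <- detect_transitions(prep)
  tr <- complexity_trace(prep)
  tab <- build_event_table(tr, ev)
  ldc_ok <- tr |>
    dplyr::filter(!is.na(ldc)) |>
    dplyr::mutate(key = paste(participant_id, day))
  n_expected <- sum(paste(ev$participant_id, ev$day) %in% ldc_ok$key)
  expect_equal(sum(tab$event), n_expected)
})

test_that("standardization is exact, reversible and error-checked", {
  rec <- simulate_eh_data(5, 60, seed = 2)
  z <- standardize_predictors(rec)
  for (v in c("time", "duration", "ldc")) {
    expect_equal(mean(z[[v]]), 0, tolerance = 1e-10)
    expect_equal(sd(z[[v]]), 1, tolerance = 1e-10)
  }
  sc <- attr(z, "scaling")
  back <- z$time * sc$sd[sc$variable == "time"] + sc$mean[sc$variable == "time"]
  expect_equal(back, rec$time)

  rec$time <- 5
  expect_error(standardize_predictors(rec), "zero variance.*time")
})

test_that("standardized-fit OR per 1 SD equals the rescaled raw-scale coefficient", {
  rec <- simulate_eh_data(40, 120, beta_ldc = 0.5, re_sd = 0.3, seed = 9)
  rec$ldc <- 0.05 + 0.02 * rec$ldc # put LDC on a non-unit raw scale
  fit_std <- suppressWarnings(
    fit_event_model(rec, "both", standardize = TRUE, drop_singular = FALSE)
  )
  fit_raw <- suppressWarnings( # raw scale triggers harmless rescaling advice
    fit_event_model(rec, "both", standardize = FALSE, drop_singular = FALSE)
  )
  b_std <- lme4::fixef(fit_std$fit)[["ldc"]]
  b_raw <- lme4::fixef(fit_raw$fit)[["ldc"]]
  # near-equality: rescaling a predictor also reparameterizes its random
  # slope, so the identity is exact only in the fixed-effects-only limit
  expect_lt(abs(b_std - b_raw * sd(rec$ldc)), 0.02)
  glm_std <- glm(event ~ time + duration + ldc,
    data = standardize_predictors(rec), family = binomial()
  )
  glm_raw <- glm(event ~ time + duration + ldc, data = rec, family = binomial())
  expect_equal(coef(glm_std)[["ldc"]], coef(glm_raw)[["ldc"]] * sd(rec$ldc),
    tolerance = 1e-8
  )
})

test_that("with no between-participant variance the fit matches plain logistic regression", {
  rec <- simulate_eh_data(30, 150, beta_ldc = 0.4, re_sd = 0, seed = 4)
  fit <- suppressMessages(fit_event_model(rec, "both"))
  glm_fit <- glm(
    event ~ time + duration + ldc,
    data = standardize_predictors(rec), family = binomial()
  )
  expect_lt(
    max(abs(lme4::fixef(fit$fit) - coef(glm_fit))),
    0.02
  )
})

test_that("odds-ratio arithmetic and profile/Wald agreement hold", {
  rec <- simulate_eh_data(30, 120, beta_ldc = 0.4, re_sd = 0.2, seed = 6)
  fit <- suppressMessages(fit_event_model(rec, "both"))
  ors <- compute_odds_ratios(fit)
  b <- lme4::fixef(fit$fit)
  expect_equal(ors$or, exp(b[ors$term]), ignore_attr = TRUE)
  expect_true(all(ors$conf.low < ors$conf.high))
  # beta = log(1.14) exponentiates back to 1.14
  expect_equal(exp(log(1.14)), 1.14)

  prof <- compute_odds_ratios(fit, method = "profile", terms = "ldc")
  expect_equal(prof$ci_method, "profile")
  wald <- ors[ors$term == "ldc", ]
  # near-quadratic likelihood at this n: profile within 5% of Wald bounds
  expect_lt(abs(prof$conf.low - wald$conf.low) / wald$conf.low, 0.05)
  expect_lt(abs(prof$conf.high - wald$conf.high) / wald$conf.high, 0.05)
})

test_that("single-outcome models subset participants by the outcome direction", {
  trace <- dplyr::bind_rows(
    make_trace_stub("A", 120), # gains only
    make_trace_stub("B", 120), # losses only
    make_trace_stub("C", 120), # both
    make_trace_stub("D", 120) # censored
  )
  events <- tibble::tibble(
    participant_id = c("A", "A", "B", "C", "C"),
    day = c(30L, 70L, 40L, 50L, 90L),
    direction = c("gain", "gain", "loss", "gain", "loss")
  )
  tab <- build_event_table(trace, events)
  # both keeps everyone incl. censored; gains keeps A and C; losses keeps B and C
  fit_both <- suppressWarnings(suppressMessages(fit_event_model(tab, "both", drop_singular = FALSE)))
  expect_equal(fit_both$n_participants, 4)
  fit_g <- suppressWarnings(suppressMessages(fit_event_model(tab, "gains", drop_singular = FALSE)))
  expect_equal(sort(as.character(unique(fit_g$data$participant_id))), c("A", "C"))
  fit_l <- suppressWarnings(suppressMessages(fit_event_model(tab, "losses", drop_singular = FALSE)))
  expect_equal(sort(as.character(unique(fit_l$data$participant_id))), c("B", "C"))
  expect_true(fit_both$n_participants >= fit_g$n_participants)
  expect_true(fit_both$n_participants >= fit_l$n_participants)
})

test_that("degenerate model inputs error clearly", {
  rec <- simulate_eh_data(10, 60, seed = 3)
  rec0 <- rec
  rec0$event <- 0L
  rec0$gain <- 0L
  rec0$loss <- 0L
  expect_error(fit_event_model(rec0, "both"), "single class")
  one <- rec[rec$participant_id == "S001", ]
  expect_error(fit_event_model(one, "both"), "2 participants")
})

test_that("tidy and glance return well-formed summaries", {
  rec <- simulate_eh_data(25, 100, beta_ldc = 0.3, re_sd = 0.2, seed = 12)
  fit <- suppressMessages(fit_event_model(rec, "both"))
  td <- tidy(fit, exponentiate = TRUE)
  expect_setequal(td$term, c("time", "duration", "ldc"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_records, nrow(fit$data))
  expect_equal(gl$n_participants, 25)
  expect_true(is.finite(gl$logLik))
})
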