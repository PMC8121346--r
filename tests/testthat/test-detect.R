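test_that("constant and single-shift series segment exactly", {
  expect_equal(nrow(segment_series(rep(7000, 60))), 1)

  seg <- segment_series(c(rep(6000, 50), rep(9000, 50)))
  expect_equal(seg$start, c(1L, 51L))
  expect_equal(seg$level, c(6000, 9000))

  expect_warning(short <- segment_series(rep(5000, 10)), "single segment")
  expect_equal(nrow(short), 1)
})

test_that("segmentation equals the exhaustive best-split oracle on random series", {
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(20:200, 1)
      k <- sample(0:3, 1)
      bp <- if (k > 0) sort(sample(8:(n - 8), k)) else integer(0)
      lev <- 8000 * cumprod(c(1, 1 + sample(c(-1, 1), k, TRUE) * runif(k, 0.2, 0.6)))
      y <- round(lev[findInterval(seq_len(n), c(1, bp))] * exp(rnorm(n, 0, 0.15)))
      got <- suppressWarnings(segment_series(y, detection_params()))
      expect_equal(
        as.integer(got$start[-1]),
        as.integer(oracle_segment_breakpoints(y, 7, 0.01)),
        info = paste("seed", s)
      )
    })
  }
})

test_that("segmentation matches rpart on clean well-separated shifts", {
  skip_if_not_installed("rpart")
  for (s in 1:5) {
    withr::with_seed(s, {
      y <- round(c(
        rep(6000, 40), rep(10000, 35), rep(7000, 45)
      ) * exp(rnorm(120, 0, 0.05)))
      fit <- rpart::rpart(
        steps ~ day,
        data = data.frame(steps = y, day = seq_along(y)),
        control = rpart::rpart.control(
          minsplit = 14, minbucket = 7, cp = 0.01,
          maxdepth = 30, xval = 0, maxcompete = 0, maxsurrogate = 0
        )
      )
      rpart_bps <- sort(ceiling(unique(fit$splits[, "index"])))
      mine <- segment_series(y, detection_params())
      expect_equal(as.integer(mine$start[-1]), as.integer(rpart_bps))
    })
  }
})

test_that("classification applies the fraction-of-median cut", {
  seg2 <- function(l1, l2) {
    tibble::tibble(
      segment = 1:2, start = c(1L, 31L), end = c(30L, 60L),
      length = c(30L, 30L), level = c(l1, l2)
    )
  }
  ev <- classify_transitions(seg2(7000, 9200), 7000)
  expect_equal(ev$direction, "gain") # |2200| > 2100
  expect_equal(ev$day, 31L)
  expect_equal(ev$delta_steps, 2200)

  expect_equal(nrow(classify_transitions(seg2(7000, 9000), 7000)), 0) # 2000 < 2100

  seg3 <- tibble::tibble(
    segment = 1:3, start = c(1L, 31L, 61L), end = c(30L, 60L, 90L),
    length = rep(30L, 3), level = c(10000, 6500, 10000)
  )
  ev3 <- classify_transitions(seg3, 9000)
  expect_equal(ev3$direction, c("loss", "gain")) # |3500| > 2700 both ways
  expect_error(
    classify_transitions(seg2(NaN, 9200), 7000),
    "non-finite"
  )
})

test_that("a noise-free injected loss is recovered exactly; short spikes are not events", {
  cfg <- cohort_config(
    noise_sigma = 0, weekend_factor = 1,
    base_level = list(mean = 8000, sd = 0, min = 1), seed = 1
  )
  sim <- simulate_series(cfg, "P1",
    participant_seed = 1,
    force = list(length = 150, breakpoints = 70, directions = "loss", magnitudes = 0.40)
  )
  ev <- detect_transitions(sim$steps)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$day, 70L)
  expect_equal(ev$direction, "loss")

  # a 3-day +60% spike inside a stable regime fails the 7-day stability rule:
  # any segment containing it spans >= 7 days, diluting its mean to below the
  # 30%-of-median cut
  y <- rep(8000, 80)
  y[40:42] <- 8000 * 1.6
  spike_ev <- detect_transitions(make_series_tbl(y))
  expect_equal(nrow(spike_ev), 0)
})

test_that("event sets are nested as the threshold rises", {
  coh <- simulate_cohort(calibrated_cohort(n = 8, seed = 31))
  prep <- suppressMessages(suppressWarnings(prepare_steps(coh$steps)))
  keys <- lapply(c(0.20, 0.30, 0.40), function(thr) {
    ev <- detect_transitions(prep, detection_params(threshold_frac = thr))
    paste(ev$participant_id, ev$day)
  })
  expect_true(all(keys[[3]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[1]]))
})

test_that("every emitted event satisfies the magnitude and stability invariants", {
  coh <- simulate_cohort(calibrated_cohort(n = 6, seed = 17))
  prep <- suppressMessages(suppressWarnings(prepare_steps(coh$steps)))
  params <- detection_params()
  ev <- detect_transitions(prep, params)
  seg <- attr(ev, "segmentation")
  expect_true(all(abs(ev$delta_frac) >= params$threshold_frac))
  expect_true(all(seg$length >= params$min_segment_days))
  expect_true(all((ev$delta_steps > 0) == (ev$direction == "gain")))
  # segment levels equal segment means of the series
  one <- prep |> dplyr::filter(participant_id == seg$participant_id[1])
  seg1 <- seg |> dplyr::filter(participant_id == one$participant_id[1])
  lev <- purrr::map2_dbl(seg1$start, seg1$end, ~ mean(one$steps[.x:.y]))
  expect_equal(seg1$level, lev)
})
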