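test_that("analytic edge windows behave as defined", {
  expect_equal(fluctuation_intensity(rep(5, 7), 0, 10), 0)
  expect_equal(distribution_measure(rep(5, 7), 0, 10), 0)

  alternating <- rep(c(0, 10), length.out = 7)
  expect_equal(fluctuation_intensity(alternating, 0, 10), 1)

  uniform <- seq(0, 10, length.out = 7)
  expect_equal(distribution_measure(uniform, 0, 10), 1)

  # degenerate scale: 0 by convention, with a warning
  expect_warning(f0 <- fluctuation_intensity(rep(3, 7), 5, 5), "degenerate")
  expect_equal(f0, 0)
  expect_warning(d0 <- distribution_measure(rep(3, 7), 5, 5), "degenerate")
  expect_equal(d0, 0)
})

test_that("F and D match the brute-force oracle on a worked window", {
  w <- c(2, 4, 1, 5, 3, 3, 2)
  expect_equal(fluctuation_intensity(w, 0, 10), oracle_fluctuation(w, 0, 10),
    tolerance = 1e-12
  )
  expect_equal(distribution_measure(w, 0, 10), oracle_distribution(w, 0, 10),
    tolerance = 1e-12
  )
  # the run decomposition of this window gives (2+3+4+2+1)/ (10*6)
  expect_equal(fluctuation_intensity(w, 0, 10), 12 / 60)
})

test_that("F, D, C stay in [0,1] and are invariant to rescaling and time reversal", {
  withr::with_seed(42, {
    for (i in 1:200) {
      m <- sample(c(5, 7, 9), 1)
      w <- runif(m, 0, 10)
      f <- fluctuation_intensity(w, 0, 10)
      d <- distribution_measure(w, 0, 10)
      expect_true(f >= 0 && f <= 1 && d >= 0 && d <= 1)
      # linear rescaling together with the scale bounds
      expect_equal(fluctuation_intensity(3 + 20 * w, 3, 203), f, tolerance = 1e-12)
      expect_equal(distribution_measure(3 + 20 * w, 3, 203), d, tolerance = 1e-12)
      # time reversal
      expect_equal(fluctuation_intensity(rev(w), 0, 10), f, tolerance = 1e-12)
      expect_equal(distribution_measure(rev(w), 0, 10), d, tolerance = 1e-12)
    }
  })
})

test_that("the trace equals day-by-day recomputation and flags warm-up as NA", {
  withr::with_seed(7, {
    y <- round(8000 * exp(rnorm(40, 0, 0.2)))
  })
  d <- make_series_tbl(y)
  tr <- complexity_trace(d, complexity_params())
  smin <- min(y)
  smax <- max(y)
  expect_true(all(is.na(tr$C[1:6])))
  for (n in 7:40) {
    win <- y[(n - 6):n]
    expect_equal(tr$F[n], oracle_fluctuation(win, smin, smax), tolerance = 1e-12)
    expect_equal(tr$D[n], oracle_distribution(win, smin, smax), tolerance = 1e-12)
  }
  expect_equal(tr$C, tr$F * tr$D)

  # constant series: complexity identically zero where defined
  ctr <- suppressWarnings(complexity_trace(make_series_tbl(rep(9000, 20))))
  expect_true(all(ctr$C[7:20] == 0))

  expect_error(complexity_trace(make_series_tbl(rep(1, 5))), "shorter than")
})

test_that("complexity peaks inside the erratic span of a stable-then-erratic series", {
  withr::with_seed(3, {
    y <- c(8000 + rnorm(30, 0, 30), 8000 + rnorm(20, 0, 2500))
  })
  tr <- complexity_trace(make_series_tbl(y))
  expect_gt(which.max(tr$C), 30)
})

test_that("local dynamic complexity is the maximum over the preceding lag days", {
  tr <- complexity_trace(make_series_tbl(rep(c(7000, 9000), 15)))
  tr$C[9:11] <- c(0.1, 0.5, 0.3)
  expect_equal(local_dynamic_complexity(tr, day = 12, lag = 3), 0.5)
  # constant C: LDC equals it
  tr$C[7:nrow(tr)] <- 0.2
  expect_equal(local_dynamic_complexity(tr, day = 15, lag = 3), 0.2)
  # insufficient history is NA, and the day itself is excluded
  expect_true(is.na(local_dynamic_complexity(tr, day = 8, lag = 3)))

  # lag-4 LDC dominates lag-2 pointwise (max over a superset)
  withr::with_seed(11, {
    y <- round(8000 * exp(rnorm(60, 0, 0.2)))
  })
  t2 <- complexity_trace(make_series_tbl(y), complexity_params(ldc_lag_days = 2))
  t4 <- complexity_trace(make_series_tbl(y), complexity_params(ldc_lag_days = 4))
  both <- !is.na(t2$ldc) & !is.na(t4$ldc)
  expect_true(all(t4$ldc[both] >= t2$ldc[both]))
})

test_that("implementation and oracle agree to 1e-12 on many random windows", {
  withr::with_seed(123, {
    for (i in 1:300) {
      w <- round(runif(7, 0, 15000))
      expect_equal(fluctuation_intensity(w, 0, 15000),
        oracle_fluctuation(w, 0, 15000),
        tolerance = 1e-12
      )
      expect_equal(distribution_measure(w, 0, 15000),
        oracle_distribution(w, 0, 15000),
        tolerance = 1e-12
      )
    }
  })
})
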