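test_that("event outcomes follow the boundary tie rule", {
  ev <- event_definition("above_median", median = 25)
  expect_equal(event_outcomes(c(10, 20, 30, 40), ev), c(0L, 0L, 1L, 1L))
  expect_equal(event_outcomes(25, ev), 0L)   # tie falls below
  # tercile 1 of [5,15,...,55] under the type-7 quantile rule: t1 boundary
  # 21.67, so exactly two values qualify
  vals <- c(5, 15, 25, 35, 45, 55)
  ev1 <- event_from_reference(vals, "tercile_1")
  expect_equal(sum(event_outcomes(vals, ev1)), 2)
  ev3 <- event_from_reference(vals, "tercile_3")
  expect_equal(sum(event_outcomes(vals, ev3)), 2)
})

test_that("forecast probabilities count members under the same tie rule", {
  ev <- event_definition("above_median", median = 55)
  expect_equal(forecast_probability(c(30, 50, 70, 90), ev), 0.5)
  expect_equal(forecast_probability(c(60, 70, 80), ev), 1)
  set.seed(1)
  m <- rnorm(50, 50, 20)
  p_above <- forecast_probability(m, ev)
  expect_equal(p_above + mean(m <= 55), 1)   # complement rule
  expect_error(forecast_probability(numeric(0), ev),
               class = "cropval_input_error")
})

test_that("Brier skill score matches hand computation and its limits", {
  b <- brier_skill_score(c(0.8, 0.2), c(1, 0), 0.5)
  expect_equal(b$BS, 0.04)
  expect_equal(b$BS_ref, 0.25)
  expect_equal(b$BSS, 0.84)
  out <- c(1, 0, 1, 1, 0)
  expect_equal(brier_skill_score(rep(0.5, 5), out, 0.5)$BSS, 0)
  expect_equal(brier_skill_score(out, out, 0.5)$BSS, 1)
  # oracle equivalence with an explicit per-item loop
  set.seed(2)
  for (k in 1:10) {
    p <- runif(40); o <- rbinom(40, 1, 0.5)
    naive <- 0
    for (i in 1:40) naive <- naive + (p[i] - o[i])^2
    expect_equal(brier_skill_score(p, o, 0.5)$BS, naive / 40,
                 tolerance = 1e-12)
  }
  # moving a probability toward its outcome strictly improves BSS
  p <- c(0.6, 0.3, 0.7); o <- c(1, 0, 1)
  p2 <- p + c(0.2, -0.2, 0)
  expect_gt(brier_skill_score(p2, o, 0.5)$BSS,
            brier_skill_score(p, o, 0.5)$BSS)
  expect_error(brier_skill_score(c(0, 1), c(0, 0), 0),
               class = "cropval_undefined_skill")
})

test_that("percent consistent favours, excludes and counts correctly", {
  pc <- percent_consistent(c(0.9, 0.8, 0.2, 0.4), c(1, 1, 0, 1), 0.5)
  expect_equal(as.numeric(pc), 75)
  expect_equal(as.numeric(percent_consistent(rep(1, 4), rep(1, 4), 0.5)),
               100)
  pc2 <- percent_consistent(c(0.9, 0.5, 0.2), c(1, 1, 0), 0.5)
  expect_equal(attr(pc2, "n_considered"), 2L)
  expect_equal(attr(pc2, "n_excluded"), 1L)
  expect_warning(out <- percent_consistent(rep(0.5, 3), c(1, 0, 1), 0.5))
  expect_true(is.na(out))
})

test_that("running skill windows agree with direct per-window calls", {
  set.seed(3)
  years <- 1981:2015
  p <- runif(35); o <- rbinom(35, 1, 0.5)
  rs <- running_skill(p, o, years, window_years = 30, metric = "bss")
  expect_equal(nrow(rs), 6)
  expect_equal(rs$end_year, 2010:2015)
  for (i in seq_len(nrow(rs))) {
    keep <- years > rs$end_year[i] - 30 & years <= rs$end_year[i]
    expect_equal(rs$value[i],
                 brier_skill_score(p[keep], o[keep], 0.5)$BSS)
  }
  o1 <- rep(c(0, 1), length.out = 35)
  rc <- running_skill(rep(0.4, 35), o1, years, metric = "percent_consistent")
  expect_equal(length(unique(round(rc$value, 9))), 1)
  expect_error(running_skill(p[1:10], o[1:10], years[1:10]),
               class = "cropval_input_error")
})

test_that("reliability summary: perfect two-point forecasts and conservation", {
  p <- rep(c(0, 1), each = 10)
  o <- rep(c(0, 1), each = 10)
  rel <- reliability_curve(p, o)
  expect_equal(rel$slope_b, 1, tolerance = 1e-9)
  expect_equal(rel$rmse, 0, tolerance = 1e-9)
  expect_equal(nrow(rel$bins), 2)
  expect_equal(rel$bins$obs_freq, c(0, 1))
  expect_equal(sum(rel$sharpness_histogram), rel$n)
  expect_error(reliability_curve(rep(0.55, 20), rbinom(20, 1, 0.5)),
               class = "cropval_undefined_slope")
})

test_that("shift and dispersion summarize location and variance changes", {
  x <- c(80, 120, 160)
  same <- shift_dispersion(x, x)
  expect_equal(same$AMD, 0)
  expect_equal(same$VR, 1)
  shifted <- shift_dispersion(x + 20, x)
  expect_equal(shifted$AMD, 20)
  expect_equal(shifted$VR, 1)
  hand <- shift_dispersion(c(100, 120, 140), c(80, 120, 160))
  expect_equal(hand$AMD, 0)
  expect_equal(hand$VR, 0.25)   # sample variances 400 / 1600
  expect_error(shift_dispersion(x, c(5, 5, 5)),
               class = "cropval_undefined_vr")
})

test_that("yield-event skill is perfect for a clairvoyant ensemble and order-invariant", {
  set.seed(4)
  designs <- data.table::data.table(maturity = "medium",
                                    tillering = "medium", density = 5,
                                    row_config = "solid", n_rate = 50)
  years <- 2001:2020
  obs <- matrix(runif(20, 1, 6), 1)
  ens <- list(matrix(rep(obs[1, ], 5), ncol = 5))   # members == observed
  rec <- make_records(designs, years, obs, ens)
  vs <- yield_event_skill(rec, events = "above_median")
  expect_equal(vs$BSS, 1)
  expect_equal(vs$n, 20L)
  shuffled <- rec[sample.int(nrow(rec))]
  expect_equal(yield_event_skill(shuffled, events = "above_median")$BSS, 1)
})
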