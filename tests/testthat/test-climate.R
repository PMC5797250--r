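test_that("weather generation is deterministic and honours invariants", {
  enso <- generate_enso_index(0.8, 5, seed = 3, start_year = 2000)
  p <- climate_params(seed = 4)
  w1 <- generate_daily_weather(p, 5, enso, start_year = 2000)
  w2 <- generate_daily_weather(p, 5, enso, start_year = 2000)
  expect_identical(w1$rain, w2$rain)
  expect_identical(w1$maxt, w2$maxt)
  expect_silent(validate_daily_weather(w1))
  expect_true(all(diff(as.integer(w1$date)) == 1L))
  expect_true(all(w1$maxt >= w1$mint))
  expect_true(all(w1$radn > 0))
})

test_that("zero wet-day probability yields a completely dry series", {
  enso <- generate_enso_index(0.5, 3, seed = 1, start_year = 2000)
  p <- climate_params(wet_day_prob_by_month = rep(0, 12),
                      rain_scale_by_month = rep(1, 12), seed = 1)
  w <- generate_daily_weather(p, 3, enso, start_year = 2000)
  expect_true(all(w$rain == 0))
})

test_that("ENSO-like index is standardized AR(1) with the requested persistence", {
  e0 <- generate_enso_index(0, 100, seed = 5)   # 1200 months
  r0 <- cor(e0$index[-1], e0$index[-nrow(e0)])
  expect_lt(abs(r0), 0.1)
  e9 <- generate_enso_index(0.9, 100, seed = 6)
  r9 <- cor(e9$index[-1], e9$index[-nrow(e9)])
  expect_gt(r9, 0.8)
  expect_lt(r9, 0.95)
  expect_lt(abs(mean(e9$index)), 0.5)
  expect_lt(abs(sd(e9$index) - 10), 0.5)
  expect_error(generate_enso_index(1, 10), class = "cropval_parameter_error")
})

test_that("teleconnection and summer fraction are recovered at 500 years", {
  enso <- generate_enso_index(0.8, 501, seed = 7, start_year = 1301)
  p <- climate_params(teleconnection_strength = 0.6, seed = 8)
  w <- generate_daily_weather(p, 501, enso, start_year = 1301)
  lt <- as.POSIXlt(w$date)
  yr <- lt$year + 1900L
  mo <- lt$mon + 1L
  yrs <- 1301:1800
  sf_tot <- vapply(yrs, function(y) {
    sum(w$rain[(yr == y & mo >= 9) | (yr == y + 1L & mo <= 2)])
  }, numeric(1))
  zbar <- vapply(yrs, function(y) {
    mean(enso[(year == y & month >= 9) |
                (year == y + 1L & month <= 2)]$index)
  }, numeric(1))
  expect_lt(abs(cor(sf_tot, zbar) - 0.6), 0.1)
  summer_share <- sum(w$rain[mo %in% c(9:12, 1, 2)]) / sum(w$rain)
  expect_lt(abs(summer_share - p$summer_fraction), 0.05)
})

test_that("climatology uses linear-interpolation quantiles and sample CV", {
  w <- sep_total_weather(c(10, 20, 30, 40, 50, 60))
  cl <- compute_climatology(w, windows = 9)
  expect_equal(cl$median, 35)
  expect_equal(cl$t1_upper, 10 + 50 / 3, tolerance = 1e-12)  # 26.667
  expect_equal(cl$t2_upper, 10 + 100 / 3, tolerance = 1e-12) # 43.333
  w2 <- sep_total_weather(c(100, 200, 300))
  cl2 <- compute_climatology(w2, windows = 9)
  expect_equal(cl2$mean, 200)
  expect_equal(cl2$cv, 0.5, tolerance = 1e-12)
  w3 <- sep_total_weather(c(50, 50, 50))
  expect_equal(compute_climatology(w3, windows = 9)$cv, 0)
  expect_error(compute_climatology(sep_total_weather(c(1, 2)), windows = 9),
               class = "cropval_coverage_error")
})

test_that("ensemble skill parameter sets the forecast-observation correlation", {
  fx <- long_weather()
  tot <- window_totals(fx$weather, 10)
  yrs <- as.integer(names(tot))[1:200]
  em <- ob <- numeric(length(yrs))
  for (i in seq_along(yrs)) {
    e <- generate_ensemble_forecast(fx$weather,
                                    sprintf("%d-10-01", yrs[i]), 0.7,
                                    n_members = 99, params = fx$params,
                                    seed = 3000 + i, traces = FALSE,
                                    totals_by_year = tot)
    em[i] <- mean(e$totals)
    ob[i] <- tot[[as.character(yrs[i])]]
  }
  expect_lt(abs(cor(em, ob) - 0.7), 0.1)
})

test_that("ensemble limits: perfect skill reproduces the observation, zero skill climatology", {
  fx <- long_weather()
  tot <- window_totals(fx$weather, 10)
  y <- as.integer(names(tot))[30]
  e1 <- generate_ensemble_forecast(fx$weather, sprintf("%d-10-01", y), 1,
                                   n_members = 20, params = fx$params,
                                   seed = 9)
  expect_equal(unname(e1$totals), rep(tot[[as.character(y)]], 20))
  obs_win <- fx$weather[fx$weather$date %in%
                          e1$members[member == 1]$date]
  expect_equal(e1$members[member == 7]$rain, obs_win$rain)

  # zero skill: over many issues VR tends to 1 and AMD to a small value
  yrs <- as.integer(names(tot))[1:150]
  amd <- vr <- numeric(length(yrs))
  for (i in seq_along(yrs)) {
    e0 <- generate_ensemble_forecast(fx$weather,
                                     sprintf("%d-10-01", yrs[i]), 0,
                                     n_members = 99, params = fx$params,
                                     seed = 5000 + i, traces = FALSE,
                                     totals_by_year = tot)
    sdp <- shift_dispersion(e0$totals, unname(tot))
    amd[i] <- sdp$AMD; vr[i] <- sdp$VR
  }
  expect_lt(abs(mean(vr) - 1), 0.15)
  expect_lt(mean(amd) / mean(tot), 0.25)
})

test_that("member daily traces sum to the member totals", {
  fx <- long_weather()
  tot <- window_totals(fx$weather, 11)
  y <- as.integer(names(tot))[10]
  e <- generate_ensemble_forecast(fx$weather, sprintf("%d-11-01", y), 0.5,
                                  n_members = 20, params = fx$params,
                                  seed = 77)
  sums <- e$members[, .(t = sum(rain)), by = member]$t
  expect_equal(sums, e$totals, tolerance = 1e-9)
  expect_equal(nrow(e$members), 20L * length(unique(e$members$date)))
})

test_that("issued above-median probabilities are reliable for all skill levels", {
  fx <- long_weather()
  tot <- window_totals(fx$weather, 10)
  yrs <- as.integer(names(tot))[1:150]
  windows <- c(9, 10)
  for (rho in c(0, 0.5, 1)) {
    probs <- out <- numeric(0); k <- 0
    for (m in windows) {
      tm <- window_totals(fx$weather, m)
      ev <- event_from_reference(unname(tm), "above_median")
      for (y in yrs) {
        k <- k + 1
        e <- generate_ensemble_forecast(fx$weather,
                                        sprintf("%d-%02d-01", y, m), rho,
                                        n_members = 99, params = fx$params,
                                        seed = 7000 + 100 * m + k,
                                        traces = FALSE, totals_by_year = tm)
        probs[k] <- forecast_probability(e$totals, ev)
        out[k] <- event_outcomes(tm[[as.character(y)]], ev)
      }
    }
    # per-0.1-bin observed frequency within binomial 99% bounds of the
    # bin's mean issued probability
    bin <- pmin(pmax(findInterval(probs, seq(0, 1, 0.1),
                                  rightmost.closed = TRUE), 1L), 10L)
    for (b in unique(bin)) {
      sel <- bin == b
      if (sum(sel) < 5) next
      pbar <- mean(probs[sel]); nb <- sum(sel)
      lo <- qbinom(0.005, nb, pbar) / nb
      hi <- qbinom(0.995, nb, pbar) / nb
      expect_gte(mean(out[sel]), lo - 1e-9)
      expect_lte(mean(out[sel]), hi + 1e-9)
    }
  }
})
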