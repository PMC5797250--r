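test_that("phase classification is nearest-centroid with fixed tie-break", {
  expect_equal(classify_phase(-12, -11), "consistently_negative")
  expect_equal(classify_phase(0, 1), "near_zero")
  # derived: distances of (9, -9) to the five default centroids
  cen <- default_phase_centroids()
  d <- sqrt((9 - cen[, "prev"])^2 + (-9 - cen[, "curr"])^2)
  expect_equal(names(which.min(d)), "rapidly_falling")
  expect_equal(classify_phase(9, -9), "rapidly_falling")
  # (-5, -5) is exactly equidistant from the consistently-negative and
  # near-zero centroids; the fixed label order resolves the tie
  expect_equal(classify_phase(-5, -5), "consistently_negative")
  expect_error(classify_phase(NA, 0), class = "cropval_classification_error")
})

test_that("phase table covers every month with a defined pair", {
  enso <- generate_enso_index(0.6, 4, seed = 2, start_year = 2000)
  ph <- soi_phase_table(enso)
  expect_equal(nrow(ph), 4 * 12 - 1)
  expect_true(all(ph$phase %in% phase_labels()))
  expect_equal(ph$index_prev[-1], ph$index_curr[-nrow(ph)])
})

test_that("analogue forecast is leave-one-out with correct category arithmetic", {
  # five years, all in the same phase; Sep totals chosen so the analogue
  # distribution of the 2005 issue is [30, 50, 70, 90] with median 55
  w <- sep_total_weather(c(30, 50, 70, 90, 55), start_year = 2001)
  enso <- generate_enso_index(0.5, 5, seed = 1, start_year = 2001)
  enso[, index := 0.01]   # every month near_zero
  fc <- analogue_forecast(w, enso, list(year = 2005, month = 9))
  expect_equal(sort(fc$analogue_years), 2001:2004)
  expect_false(2005 %in% fc$analogue_years)
  expect_equal(sort(fc$distribution), c(30, 50, 70, 90))
  expect_equal(unname(fc$category_probs[["p_above"]]), 0.5)
  expect_equal(fc$category_probs[["p_above"]] +
                 fc$category_probs[["p_below"]], 1)
  expect_equal(sum(fc$category_probs[c("p_t1", "p_t2", "p_t3")]), 1,
               tolerance = 1e-12)
})

test_that("empty analogue sets error or fall back to climatology", {
  w <- sep_total_weather(c(30, 50, 70, 90, 55), start_year = 2001)
  enso <- generate_enso_index(0.5, 5, seed = 1, start_year = 2001)
  enso[, index := 0.01]
  # make the 2005 issue-month pair unique (consistently positive)
  enso[year == 2005 & month %in% c(8, 9), index := 40]
  expect_error(
    analogue_forecast(w, enso, list(year = 2005, month = 9),
                      fallback = FALSE),
    class = "cropval_insufficient_analogues")
  fc <- analogue_forecast(w, enso, list(year = 2005, month = 9))
  expect_true(fc$fallback)
  expect_equal(sort(fc$analogue_years), 2001:2004)
})

test_that("every hindcast issue excludes its own year and conserves probability", {
  fx <- long_weather()
  short <- fx$weather[fx$weather$date <= as.Date("1840-12-31")]
  data.table::setattr(short, "class", class(fx$weather))
  enso <- fx$enso[year <= 1840]
  ah <- analogue_hindcast(short, enso, months = c(9, 1))
  expect_gt(nrow(ah), 60)
  expect_true(all(ah$p_above >= 0 & ah$p_above <= 1))
  ph <- soi_phase_table(enso)
  for (i in sample.int(nrow(ah), 12)) {
    fc <- analogue_forecast(short, enso,
                            list(year = ah$year[i], month = ah$month[i]),
                            phase_table = ph)
    expect_false(ah$year[i] %in% fc$analogue_years)
    expect_equal(sum(fc$category_probs[c("p_t1", "p_t2", "p_t3")]), 1,
                 tolerance = 1e-12)
  }
})
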