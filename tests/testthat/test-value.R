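test_that("profit decomposition matches the printed cost structure", {
  expect_equal(profit(0, TRUE), -161)
  # 4 t/ha harvested at base nitrogen: 4*254 - 1% - 211
  expect_equal(profit(4, FALSE), 4 * 254 - 0.01 * 4 * 254 - 211)
  expect_equal(profit(4, FALSE), 794.84)
  # linearity in yield at 1 - insurance
  d <- profit(8, FALSE) - profit(4, FALSE)
  expect_equal(d, 4 * 254 * 0.99)
  # incremental nitrogen priced as urea
  expect_equal(profit(4, FALSE, n_rate = 150) - profit(4, FALSE, n_rate = 50),
               -100 * 0.30 / 0.46)
})

test_that("downside risk is a strict-threshold exceedance percentage", {
  expect_equal(downside_risk(c(700, 800)), 0)
  expect_equal(downside_risk(c(500, 700, 650, 400)), 50)
  expect_equal(downside_risk(rep(600, 5)), 0)   # strict inequality
  expect_error(downside_risk(numeric(0)), class = "cropval_input_error")
})

test_that("crop-year enumeration reproduces the full-study count", {
  expect_equal(count_crop_year_simulations(), 176256000)
  one <- list(locations = 1, windows = 1, soils = 1, isw = 1,
              row_configs = 1, densities = 1, n_rates = 1, maturities = 1,
              tillering = 1, n_years = 1, n_traces = 1)
  expect_equal(count_crop_year_simulations(one), 1)
  small <- one
  small$windows <- 2; small$densities <- 2; small$n_years <- 3
  expect_equal(count_crop_year_simulations(small), 12)
  bad <- one; bad$soils <- NULL
  expect_error(count_crop_year_simulations(bad),
               class = "cropval_config_error")
})

test_that("static optimizer equals brute force on a seeded 100-design instance", {
  set.seed(11)
  lv <- design_levels()
  all_designs <- data.table::as.data.table(
    expand.grid(maturity = lv$maturity, tillering = lv$tillering,
                density = lv$density, row_config = lv$row_config,
                n_rate = lv$n_rate, stringsAsFactors = FALSE))
  designs <- all_designs[sample(.N, 100)]
  years <- 2001:2012
  obs <- matrix(runif(100 * 12, 0.5, 7), 100)
  rec <- make_records(designs, years, obs)
  econ <- econ_params()
  so <- optimize_static(rec, econ)
  # independent brute force over designs
  means <- vapply(seq_len(100), function(i)
    mean(profit(obs[i, ], obs[i, ] < 0.2, designs$n_rate[i], econ)),
    numeric(1))
  best <- which.max(means)
  expect_equal(unname(so$design_by_year[1]),
               design_id_of(designs$maturity[best], designs$tillering[best],
                            designs$density[best],
                            designs$row_config[best], designs$n_rate[best]))
  expect_equal(so$mean_profit, max(means))
  # adding a dominated design changes nothing
  dom <- rbind(rec,
               make_records(data.table::data.table(
                 maturity = "late", tillering = "high", density = 3.5,
                 row_config = "single_skip", n_rate = 150),
                 years, matrix(0.01, 1, 12)))
  expect_equal(optimize_static(dom, econ)$design_by_year,
               so$design_by_year)
})

test_that("perfect knowledge dominates static choice year by year", {
  set.seed(12)
  designs <- data.table::as.data.table(expand.grid(
    maturity = c("early", "medium"), tillering = c("none", "medium"),
    density = c(5, 8), row_config = "solid", n_rate = c(50, 150),
    stringsAsFactors = FALSE))
  years <- 2001:2015
  obs <- matrix(runif(nrow(designs) * 15, 0.5, 7), nrow(designs))
  rec <- make_records(designs, years, obs)
  econ <- econ_params()
  pk <- perfect_knowledge(rec, econ)
  so <- optimize_static(rec, econ)
  expect_true(all(pk$profits >= so$profits - 1e-9))
  # brute-force per-year argmax
  pmat <- vapply(seq_len(nrow(designs)), function(i)
    profit(obs[i, ], obs[i, ] < 0.2, designs$n_rate[i], econ), numeric(15))
  expect_equal(unname(pk$profits), apply(pmat, 1, max))
})

test_that("the BSS filter removes anti-skilled designs from the search", {
  years <- 2001:2020
  # design A: anti-correlated ensemble but the higher ensemble-mean yield;
  # design B: clairvoyant ensemble
  obs_a <- rep(c(1, 3), 10)
  obs_b <- rep(c(1.5, 2.5), 10)
  ens_a <- matrix(rep(ifelse(obs_a > 2, 1, 3), 5), ncol = 5)  # wrong way
  ens_b <- matrix(rep(obs_b, 5), ncol = 5)                    # perfect
  designs <- data.table::data.table(
    maturity = c("medium", "early"), tillering = c("medium", "none"),
    density = c(5, 5), row_config = c("solid", "solid"), n_rate = c(50, 50))
  rec <- make_records(designs, years, rbind(obs_a, obs_b),
                      list(ens_a, ens_b))
  fo <- select_forecast_designs(rec)
  b_id <- design_id_of("early", "none", 5, "solid", 50)
  expect_equal(attr(fo, "kept_designs"), b_id)
  expect_true(all(fo$design_by_year == b_id))
  expect_false(attr(fo, "bss_fallback"))
})

test_that("value-report identities hold and mismatched years are rejected", {
  set.seed(13)
  designs <- data.table::as.data.table(expand.grid(
    maturity = c("early", "medium"), tillering = "medium",
    density = c(5, 8), row_config = "solid", n_rate = c(50, 150),
    stringsAsFactors = FALSE))
  years <- 2001:2015
  obs <- matrix(runif(nrow(designs) * 15, 0.5, 7), nrow(designs))
  ens <- lapply(seq_len(nrow(designs)), function(i)
    matrix(obs[i, ] + rnorm(15 * 7, 0, 0.3), 15, 7))
  rec <- make_records(designs, years, obs, ens)
  econ <- econ_params()
  fp <- farmer_profile(rec, crop_design(), econ)
  so <- optimize_static(rec, econ)
  fo <- select_forecast_designs(rec, econ)
  pk <- perfect_knowledge(rec, econ)
  vr <- value_report(fp, so, fo, pk)
  expect_equal(vr$value_optS, so$mean_profit - fp$mean_profit,
               tolerance = 1e-9)
  expect_equal(vr$value_optSCF, fo$mean_profit - so$mean_profit,
               tolerance = 1e-9)
  expect_equal(vr$value_PK, pk$mean_profit - fp$mean_profit,
               tolerance = 1e-9)
  expect_gte(vr$value_PK, vr$value_optS)
  expect_gte(so$mean_profit, fp$mean_profit)
  # mismatched year sets
  rec2 <- make_records(designs, 2002:2016, obs)
  so2 <- optimize_static(rec2, econ)
  expect_error(value_report(fp, so2), class = "cropval_input_error")
})

test_that("worked value arithmetic recovers the printed site-by-soil cells", {
  cells <- list(c(1108, 1260, 152), c(1127, 1337, 210),
                c(866, 1092, 226), c(373, 427, 54))
  for (cell in cells) {
    pr <- constant_profit_profiles(cell[1], cell[2])
    vr <- value_report(pr$farmer, pr$static_optimal)
    expect_equal(pr$farmer$mean_profit, cell[1], tolerance = 1e-9)
    expect_equal(vr$value_optS, cell[3], tolerance = 1e-9)
  }
})
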