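# shared fixtures, built lazily and cached for the whole test run
.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# long teleconnected synthetic record for Monte Carlo checks
long_weather <- function() {
  fixture("long", function() {
    enso <- generate_enso_index(0.8, 220, seed = 101, start_year = 1801)
    params <- climate_params(teleconnection_strength = 0.3, seed = 102)
    list(enso = enso, params = params,
         weather = generate_daily_weather(params, 220, enso,
                                          start_year = 1801))
  })
}

# hand-built daily weather: gap-free dates, rain set by rain_fun(date)
manual_weather <- function(years, rain_fun = function(date) 0,
                           site_id = "manual") {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  dt <- data.table::data.table(date = dates,
                               rain = vapply(dates, rain_fun, numeric(1)),
                               maxt = 30, mint = 15, radn = 20)
  data.table::setattr(dt, "class",
                      c("daily_weather", class(data.table::data.table())))
  data.table::setattr(dt, "site_id", site_id)
  dt
}

# weather whose September totals are exactly `totals` (all rain on Sep 1)
sep_total_weather <- function(totals, start_year = 2001L) {
  yrs <- start_year + seq_along(totals) - 1L
  lut <- stats::setNames(totals, as.character(yrs))
  manual_weather(yrs, function(d) {
    if (format(d, "%m-%d") == "09-01") {
      v <- lut[[format(d, "%Y")]]
      if (is.null(v)) 0 else v
    } else 0
  })
}

design_id_of <- function(maturity, tillering, density, row_config, n_rate) {
  paste(maturity, tillering, density, row_config, n_rate, sep = "|")
}

# yield-record table from explicit per-design yields.
# designs: data.table with the five design columns;
# obs_yields: matrix [design x year]; ens_yields: optional list (one per
# design) of matrices [year x member]
make_records <- function(designs, years, obs_yields, ens_yields = NULL,
                         fail_thresh = 0.2) {
  rows <- list()
  for (i in seq_len(nrow(designs))) {
    d <- designs[i]
    rows[[length(rows) + 1L]] <- data.table::data.table(
      site = "toy", soil = "soil", isw = 0.6, window = 10L,
      maturity = d$maturity, tillering = d$tillering, density = d$density,
      row_config = d$row_config, n_rate = d$n_rate,
      year = years, trace = 0L, yield = obs_yields[i, ],
      failed = obs_yields[i, ] < fail_thresh)
    if (!is.null(ens_yields)) {
      em <- ens_yields[[i]]
      for (m in seq_len(ncol(em))) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          site = "toy", soil = "soil", isw = 0.6, window = 10L,
          maturity = d$maturity, tillering = d$tillering,
          density = d$density, row_config = d$row_config,
          n_rate = d$n_rate, year = years, trace = m,
          yield = em[, m], failed = em[, m] < fail_thresh)
      }
    }
  }
  data.table::rbindlist(rows)
}

# strategy profile with a constant profit level, via records whose yields
# realize that profit exactly (used for worked value arithmetic)
constant_profit_profiles <- function(mean_farmer, mean_opt,
                                     years = 1981:2015) {
  econ <- econ_params()
  y_of <- function(target) (target + econ$cost_harvested) /
    (econ$price * (1 - econ$insurance_rate))
  designs <- data.table::data.table(
    maturity = c("medium", "early"), tillering = c("medium", "none"),
    density = c(5, 5), row_config = c("solid", "solid"),
    n_rate = c(50, 50))
  obs <- rbind(rep(y_of(mean_farmer), length(years)),
               rep(y_of(mean_opt), length(years)))
  rec <- make_records(designs, years, obs)
  list(farmer = farmer_profile(rec, crop_design(), econ),
       static_optimal = optimize_static(rec, econ))
}

# tiny end-to-end pipeline configuration (fast)
tiny_config <- function(seed = 7L) {
  experiment_config(
    sites = list(Tiny = list(annual_rain_mean = 650, summer_fraction = 0.64,
                             teleconnection_strength = 0.3,
                             soils = list(high = 350))),
    start_year = 1991L, n_years = 3L, windows = 10L, isw_levels = 0.6,
    maturities = "medium", tillering = "medium", densities = 5,
    row_configs = "solid", n_rates = c(50, 150), n_members = 3L,
    skill_rho = 0.5, value_window = 10L, value_isw = 0.6, seed = seed)
}
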