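#' Parameters for the stochastic daily weather generator
#'
#' Builds and validates the parameter block of the synthetic climate
#' generator. Rainfall occurrence follows a first-order two-state Markov
#' chain with a stationary monthly wet-day probability; wet-day amounts are
#' gamma distributed with a monthly scale; seasonal rainfall is modulated
#' multiplicatively by a standardized ENSO-like index so that the
#' correlation between Sep--Feb rainfall totals and the mean Sep--Feb index
#' equals `teleconnection_strength` (calibrated by closed-form variance
#' accounting, see [generate_daily_weather()]).
#'
#' Monthly mean rainfall is `annual_rain_mean` split across months by a
#' fixed within-half-year shape scaled by `summer_fraction` (the share of
#' annual rain falling in September--February). The monthly gamma scales are
#' derived from those means unless supplied directly.
#'
#' @param annual_rain_mean mean annual rainfall, mm.
#' @param summer_fraction share of annual rain in Sep--Feb, in (0, 1).
#' @param wet_day_prob_by_month 12 stationary wet-day probabilities
#'   (Jan..Dec).
#' @param rain_shape gamma shape of wet-day amounts (> 0).
#' @param rain_scale_by_month optional 12 gamma scales (mm); derived from
#'   the monthly means when `NULL`.
#' @param wet_persistence lag-1 correlation of the occurrence chain, in
#'   `[0, 1)`.
#' @param temp_harmonic named vector `c(mean, amplitude, phase_doy)` for the
#'   daily maximum temperature harmonic (degC, degC, day of year of the
#'   warmest day).
#' @param temp_range_mean,temp_range_sd mean and sd of the diurnal range
#'   (degC); the range is truncated below at 2 degC so `maxt >= mint` always.
#' @param temp_noise_sd daily noise sd on maximum temperature (degC).
#' @param radn_mean,radn_amplitude,radn_noise_sd solar radiation harmonic
#'   and noise (MJ m-2); radiation is truncated below at 1.
#' @param teleconnection_strength target correlation of Sep--Feb rainfall
#'   totals with the mean Sep--Feb index, in `[-1, 1]`.
#' @param seed integer seed; every generator output is a pure function of
#'   (params, seed).
#' @param site_id site label carried into generated series.
#' @return an object of class `climate_params` (a validated list).
#' @export
climate_params <- function(annual_rain_mean = 670,
                           summer_fraction = 0.64,
                           wet_day_prob_by_month = NULL,
                           rain_shape = 0.75,
                           rain_scale_by_month = NULL,
                           wet_persistence = 0.25,
                           temp_harmonic = c(mean = 26, amplitude = 6.5,
                                             phase_doy = 15),
                           temp_range_mean = 13, temp_range_sd = 2,
                           temp_noise_sd = 2.5,
                           radn_mean = 20, radn_amplitude = 7,
                           radn_noise_sd = 3,
                           teleconnection_strength = 0.3,
                           seed = 1L,
                           site_id = "synthetic") {
  .assert(is.numeric(annual_rain_mean) && annual_rain_mean > 0,
          "annual_rain_mean must be > 0", "cropval_parameter_error")
  .assert(summer_fraction > 0 && summer_fraction < 1,
          "summer_fraction must be in (0, 1)", "cropval_parameter_error")
  .assert(rain_shape > 0, "rain_shape must be > 0", "cropval_parameter_error")
  .assert(wet_persistence >= 0 && wet_persistence < 1,
          "wet_persistence must be in [0, 1)", "cropval_parameter_error")
  .assert(abs(teleconnection_strength) <= 1,
          "teleconnection_strength must be in [-1, 1]",
          "cropval_parameter_error")

  if (is.null(wet_day_prob_by_month)) {
    wet_day_prob_by_month <- c(0.26, 0.24, 0.22, 0.16, 0.15, 0.15,
                               0.13, 0.13, 0.16, 0.21, 0.24, 0.26)
  }
  .assert(length(wet_day_prob_by_month) == 12 &&
            all(wet_day_prob_by_month >= 0 & wet_day_prob_by_month <= 1),
          "wet_day_prob_by_month must be 12 probabilities in [0, 1]",
          "cropval_parameter_error")

  # monthly mean rainfall from the half-year shapes
  w <- numeric(12)
  w[.summer_months] <- summer_fraction *
    .summer_shape[match(.summer_months, c(9, 10, 11, 12, 1, 2))]
  winter <- setdiff(1:12, .summer_months)
  w[winter] <- (1 - summer_fraction) *
    .winter_shape[match(winter, 3:8)]
  monthly_mean <- annual_rain_mean * w

  if (is.null(rain_scale_by_month)) {
    expected_wet <- .month_days(1:12) * wet_day_prob_by_month
    rain_scale_by_month <- ifelse(expected_wet > 0,
                                  monthly_mean / (expected_wet * rain_shape),
                                  1)
  }
  .assert(length(rain_scale_by_month) == 12 && all(rain_scale_by_month > 0),
          "rain_scale_by_month must be 12 positive scales",
          "cropval_parameter_error")

  structure(list(
    annual_rain_mean = annual_rain_mean,
    summer_fraction = summer_fraction,
    monthly_mean_rain = monthly_mean,
    wet_day_prob_by_month = as.numeric(wet_day_prob_by_month),
    rain_shape = rain_shape,
    rain_scale_by_month = as.numeric(rain_scale_by_month),
    wet_persistence = wet_persistence,
    temp_harmonic = temp_harmonic,
    temp_range_mean = temp_range_mean, temp_range_sd = temp_range_sd,
    temp_noise_sd = temp_noise_sd,
    radn_mean = radn_mean, radn_amplitude = radn_amplitude,
    radn_noise_sd = radn_noise_sd,
    teleconnection_strength = teleconnection_strength,
    seed = as.integer(seed), site_id = site_id
  ), class = "climate_params")
}

#' @export
print.climate_params <- function(x, ...) {
  cat("<climate_params>", x$site_id, "\n")
  cat("  annual rain", x$annual_rain_mean, "mm, summer fraction",
      x$summer_fraction, "\n")
  cat("  teleconnection", x$teleconnection_strength, " seed", x$seed, "\n")
  invisible(x)
}

#' Generate a persistent standardized ENSO-like monthly index
#'
#' Stationary AR(1) series, standardized over the generated period to mean 0
#' and standard deviation 10 (the conventional pressure-index scale).
#'
#' @param ar1_coeff AR(1) persistence, |ar1_coeff| < 1.
#' @param n_years number of calendar years (12 values each).
#' @param seed integer seed.
#' @param start_year first calendar year label.
#' @return an `enso_index` data.table with columns `year`, `month`, `index`.
#' @export
generate_enso_index <- function(ar1_coeff, n_years, seed = 1L,
                                start_year = 1981L) {
  .assert(abs(ar1_coeff) < 1, "|ar1_coeff| must be < 1",
          "cropval_parameter_error")
  .assert(n_years >= 1, "n_years must be >= 1", "cropval_parameter_error")
  n <- as.integer(n_years) * 12L
  set.seed(as.integer(seed))
  e <- rnorm(n, sd = sqrt(1 - ar1_coeff^2))
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in seq_len(n - 1L)) x[i + 1L] <- ar1_coeff * x[i] + e[i + 1L]
  x <- (x - mean(x)) / sd(x) * 10
  out <- data.table(
    year = rep(start_year + seq_len(n_years) - 1L, each = 12L),
    month = rep(1:12, n_years),
    index = x
  )
  setattr(out, "class", c("enso_index", class(data.table())))
  setattr(out, "ar1_coeff", ar1_coeff)
  setattr(out, "seed", as.integer(seed))
  out[]
}

# closed-form variance accounting for the ENSO modulation coefficient beta:
# monthly gamma scale is multiplied by (1 + beta * z) with z the index on
# unit-variance scale, and beta is chosen so that the model correlation of
# Sep-Feb totals with the mean Sep-Feb index equals the target.
.calibrate_teleconnection <- function(params, ar1) {
  lambda <- params$teleconnection_strength
  if (lambda == 0) return(0)
  mths <- c(9L, 10L, 11L, 12L, 1L, 2L)   # consecutive, lag 1 apart
  mu <- params$monthly_mean_rain[mths]
  p <- params$wet_day_prob_by_month[mths]
  nd <- .month_days(mths)
  k <- params$rain_shape
  th <- params$rain_scale_by_month[mths]
  r <- params$wet_persistence
  ma <- k * th; va <- k * th^2
  v0m <- nd * p * va + ma^2 * nd * p * (1 - p) * (1 + r) / (1 - r)
  V0 <- sum(v0m)
  G <- outer(1:6, 1:6, function(i, j) ar1^abs(i - j))
  A <- sum(mu * rowSums(G)) / 6
  B <- as.numeric(t(mu) %*% G %*% mu)
  sz2 <- sum(G) / 36
  den <- A^2 - lambda^2 * sz2 * (V0 + B)
  .assert(den > 0,
          "teleconnection_strength unattainable for this climate/index",
          "cropval_parameter_error")
  sign(lambda) * sqrt(lambda^2 * sz2 * V0 / den)
}

# daily weather core: consumes the current RNG stream; mult is the per-day
# multiplier on the gamma rain scale (1 = no modulation)
.daily_core <- function(dates, params, mult) {
  n <- length(dates)
  mon <- as.POSIXlt(dates)$mon + 1L
  doy <- as.POSIXlt(dates)$yday + 1L
  p_wet <- params$wet_day_prob_by_month[mon]
  wet <- markov_occurrence_cpp(p_wet, params$wet_persistence, runif(n))
  rain <- numeric(n)
  iw <- which(wet == 1L)
  if (length(iw)) {
    rain[iw] <- rgamma(length(iw), shape = params$rain_shape,
                       scale = params$rain_scale_by_month[mon[iw]] * mult[iw])
  }
  th <- params$temp_harmonic
  seas <- cos(2 * pi * (doy - th[["phase_doy"]]) / 365.25)
  maxt <- th[["mean"]] + th[["amplitude"]] * seas +
    rnorm(n, sd = params$temp_noise_sd) - 1.5 * (wet == 1L)
  trange <- pmax(2, rnorm(n, params$temp_range_mean, params$temp_range_sd))
  mint <- maxt - trange
  radn <- params$radn_mean + params$radn_amplitude * seas +
    rnorm(n, sd = params$radn_noise_sd)
  radn <- pmax(1, radn * ifelse(wet == 1L, 0.8, 1))
  data.table(date = dates, rain = rain, maxt = maxt, mint = mint, radn = radn)
}

#' Generate a synthetic daily weather series
#'
#' Daily rainfall, temperatures and radiation for `n_years` calendar years.
#' Rain occurrence is a first-order two-state Markov chain with the
#' configured monthly wet-day probabilities; amounts are gamma; the monthly
#' gamma scale is modulated multiplicatively by the ENSO-like index so that
#' the Sep--Feb total correlates with the mean Sep--Feb index at
#' `params$teleconnection_strength`. Deterministic under a fixed seed.
#'
#' @param params a [climate_params()] object.
#' @param n_years number of calendar years (>= 1).
#' @param enso an [generate_enso_index()] series covering the same years.
#' @param start_year first calendar year.
#' @param seed seed; defaults to `params$seed`.
#' @return a `daily_weather` data.table (`date`, `rain`, `maxt`, `mint`,
#'   `radn`) with attributes `site_id` and `teleconnection_beta`.
#' @export
generate_daily_weather <- function(params, n_years, enso,
                                   start_year = 1981L, seed = NULL) {
  .assert(inherits(params, "climate_params"), "params must be climate_params",
          "cropval_parameter_error")
  .assert(n_years >= 1, "n_years must be >= 1", "cropval_parameter_error")
  years <- start_year + seq_len(n_years) - 1L
  .assert(all(years %in% unique(enso$year)),
          "enso index does not cover the requested years",
          "cropval_coverage_error")

  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  lt <- as.POSIXlt(dates)
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L

  ar1 <- attr(enso, "ar1_coeff") %||% 0.8
  beta <- .calibrate_teleconnection(params, ar1)
  y0 <- min(enso$year)
  z <- numeric(max((enso$year - y0) * 12L + enso$month))
  z[(enso$year - y0) * 12L + enso$month] <- enso$index / 10
  zday <- z[(yr - y0) * 12L + mon]
  mult <- pmax(0.05, 1 + beta * zday)

  set.seed(as.integer(seed %||% params$seed))
  out <- .daily_core(dates, params, mult)
  setattr(out, "class", c("daily_weather", class(data.table())))
  setattr(out, "site_id", params$site_id)
  setattr(out, "teleconnection_beta", beta)
  setattr(out, "seed", as.integer(seed %||% params$seed))
  validate_daily_weather(out)
  out[]
}

#' Validate a daily weather series
#'
#' Checks the invariants of the daily weather contract: strictly increasing
#' gap-free dates, non-negative rain, `maxt >= mint`, positive radiation.
#' @param x a `daily_weather` table (or any data.frame with the columns).
#' @return `x` invisibly; errors with class `cropval_input_error` otherwise.
#' @export
validate_daily_weather <- function(x) {
  .assert(all(c("date", "rain", "maxt", "mint", "radn") %in% names(x)),
          "missing weather columns", "cropval_input_error")
  d <- as.integer(x$date)
  .assert(all(diff(d) == 1L), "dates must be strictly increasing and gap-free",
          "cropval_input_error")
  .assert(all(x$rain >= 0), "rain must be >= 0", "cropval_input_error")
  .assert(all(x$maxt >= x$mint), "maxt must be >= mint", "cropval_input_error")
  .assert(all(x$radn > 0), "radn must be > 0", "cropval_input_error")
  invisible(x)
}

#' @export
print.daily_weather <- function(x, ...) {
  cat("<daily_weather>", attr(x, "site_id") %||% "?",
      format(min(x$date)), "to", format(max(x$date)),
      sprintf("(%d days)\n", nrow(x)))
  NextMethod()
}

# months of the 3-month window starting at `month` (lead 0)
.window_months <- function(month) ((month - 1L + 0:2) %% 12L) + 1L

#' Three-month window rainfall totals by start year
#'
#' Totals of the 3-month window beginning in `month` (the issue month, lead
#' 0), labelled by the calendar year of the first month. Only years whose
#' full window lies inside the series are returned.
#' @param obs a daily weather series.
#' @param month window start month (1--12).
#' @return named numeric vector of totals (mm), names = start years.
#' @export
window_totals <- function(obs, month) {
  m_start <- as.integer(month)
  .assert(m_start %in% 1:12, "month must be 1..12", "cropval_parameter_error")
  lt <- as.POSIXlt(obs$date)
  dtm <- data.table(yr = lt$year + 1900L, mo = lt$mon + 1L, rain = obs$rain)
  mtot <- dtm[, .(total = sum(rain), ndays = .N), by = .(yr, mo)]
  mtot <- mtot[ndays >= 28L]   # drop partial months at the series edges
  wm <- .window_months(m_start)
  shift_yr <- cumsum(c(0L, diff(wm) < 0))   # months that wrap into year+1
  parts <- lapply(seq_along(wm), function(i) {
    mtot[mo == wm[i], .(start_year = yr - shift_yr[i], part = total)]
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "start_year"), parts)
  tot <- rowSums(as.matrix(merged[, -1, with = FALSE]))
  setNames(tot, as.character(merged$start_year))
}

#' Climatological summary of window rainfall
#'
#' Per-window mean, median, empirical tercile boundaries and coefficient of
#' variation over a reference period. Terciles are the 1/3 and 2/3
#' linear-interpolation quantiles of the reference window totals; CV is the
#' sample (n-1) standard deviation over the mean.
#'
#' @param obs a daily weather series.
#' @param windows window start months (default all twelve).
#' @param reference_years optional subset of start years.
#' @return a `climatology` data.table with one row per window and an attr
#'   `totals` holding the reference totals per window.
#' @export
compute_climatology <- function(obs, windows = 1:12,
                                reference_years = NULL) {
  totals <- list()
  rows <- lapply(windows, function(m) {
    tot <- window_totals(obs, m)
    if (!is.null(reference_years)) {
      tot <- tot[names(tot) %in% as.character(reference_years)]
    }
    .assert(length(tot) >= 3,
            sprintf("window %d: reference period must be >= 3 years", m),
            "cropval_coverage_error")
    totals[[as.character(m)]] <<- tot
    q <- cv_quantile(tot, c(1 / 3, 0.5, 2 / 3))
    data.table(window = m, label = month.abb[m], n_years = length(tot),
               mean = mean(tot), median = q[2],
               t1_upper = q[1], t2_upper = q[3],
               cv = sd(tot) / mean(tot))
  })
  out <- rbindlist(rows)
  setattr(out, "class", c("climatology", class(data.table())))
  setattr(out, "totals", totals)
  out[]
}

#' @export
print.climatology <- function(x, ...) {
  cat("<climatology>", nrow(x), "window(s),",
      x$n_years[1], "reference years\n")
  NextMethod()
}

#' Generate a tunable-skill ensemble hindcast for one issue
#'
#' Emulates a lead-0, 3-month ensemble rainfall forecast issued on the first
#' of a month. On a variance-stabilized (square-root) scale of window
#' totals, a latent forecast signal is drawn around the realized anomaly of
#' the issue year, `s | a ~ N(rho a, 1 - rho^2)`, and member anomalies are
#' drawn from the conditional climate given the signal,
#' `x_i | s ~ N(rho s, 1 - rho^2)`. The ensemble is therefore calibrated by
#' construction, `cor(ensemble mean, observed)` tends to `rho`, at
#' `rho = 0` the members reproduce climatology and at `rho = 1` every member
#' equals the realized observation (including, at the daily scale, the
#' observed trace). Member daily traces for `rho < 1` are fresh synthetic
#' window traces rescaled so their rain sums equal the member totals.
#'
#' @param obs daily weather covering the target window (all hindcast years
#'   are used as the in-sample climatological reference).
#' @param issue_date issue date; coerced to the first of its month.
#' @param skill_rho skill parameter in `[0, 1]`.
#' @param n_members ensemble size (default 99).
#' @param params the [climate_params()] used for member trace synthesis;
#'   defaults to a generic parameter block.
#' @param seed seed for this issue.
#' @param traces synthesize member daily traces? (`FALSE` returns totals
#'   only, which is all rainfall verification needs.)
#' @param totals_by_year optional precomputed [window_totals()] for the
#'   issue window (avoids re-aggregating the observed series per issue).
#' @return an `ensemble_forecast` object: list with `totals` (mm, length
#'   `n_members`), `members` (a data.table of daily traces, or `NULL`),
#'   `issue_date`, `target_months`, `skill_rho`, `obs_total`.
#' @export
generate_ensemble_forecast <- function(obs, issue_date, skill_rho,
                                       n_members = 99L, params = NULL,
                                       seed = 1L, traces = TRUE,
                                       totals_by_year = NULL) {
  .assert(skill_rho >= 0 && skill_rho <= 1, "skill_rho must be in [0, 1]",
          "cropval_parameter_error")
  if (is.null(params)) params <- climate_params()
  issue_date <- as.Date(issue_date)
  issue_date <- as.Date(format(issue_date, "%Y-%m-01"))
  m <- as.POSIXlt(issue_date)$mon + 1L
  y <- as.POSIXlt(issue_date)$year + 1900L

  tot <- totals_by_year %||% window_totals(obs, m)
  .assert(as.character(y) %in% names(tot),
          "observations do not cover the target window",
          "cropval_coverage_error")
  sx <- sqrt(tot)
  m0 <- mean(sx); s0 <- sd(sx)
  .assert(s0 > 0, "degenerate climatology (zero variance)",
          "cropval_input_error")
  a <- (sqrt(tot[[as.character(y)]]) - m0) / s0

  set.seed(as.integer(seed))
  noise <- sqrt(1 - skill_rho^2)
  s <- skill_rho * a + noise * rnorm(1)
  x <- skill_rho * s + noise * rnorm(n_members)
  totals <- pmax(0, m0 + s0 * x)^2

  win_dates <- .window_dates(issue_date)
  members <- NULL
  if (!traces) {
    if (skill_rho == 1) totals <- rep(tot[[as.character(y)]], n_members)
  } else if (skill_rho == 1) {
    # degenerate conditional distribution: members are the observation
    obs_win <- obs[obs$date %in% win_dates,
                   c("date", "rain", "maxt", "mint", "radn"), with = FALSE]
    members <- obs_win[rep(seq_len(nrow(obs_win)), n_members)]
    members[, member := rep(seq_len(n_members), each = nrow(obs_win))]
    totals <- rep(tot[[as.character(y)]], n_members)
  } else {
    nd <- length(win_dates)
    all_dates <- rep(win_dates, n_members)
    tr <- .daily_core(all_dates, params, mult = rep(1, length(all_dates)))
    tr[, member := rep(seq_len(n_members), each = nd)]
    tr_tot <- tr[, .(tt = sum(rain)), by = member]$tt
    for (i in seq_len(n_members)) {
      idx <- ((i - 1L) * nd + 1L):(i * nd)
      if (tr_tot[i] > 0) {
        set(tr, idx, "rain", tr$rain[idx] * totals[i] / tr_tot[i])
      } else if (totals[i] > 0) {
        k <- sample(idx, min(6L, nd))
        wts <- rgamma(length(k), shape = 1)
        set(tr, k, "rain", totals[i] * wts / sum(wts))
      }
    }
    members <- tr
  }
  if (!is.null(members)) {
    setcolorder(members, c("member", "date", "rain", "maxt", "mint", "radn"))
  }

  structure(list(
    site_id = attr(obs, "site_id") %||% "site",
    issue_date = issue_date, lead = 0L,
    target_months = .window_months(m),
    skill_rho = skill_rho, n_members = as.integer(n_members),
    totals = unname(totals), members = members,
    obs_total = tot[[as.character(y)]],
    clim_sqrt = c(mean = m0, sd = s0), seed = as.integer(seed)
  ), class = "ensemble_forecast")
}

.window_dates <- function(issue_date) {
  m <- as.POSIXlt(issue_date)$mon + 1L
  y <- as.POSIXlt(issue_date)$year + 1900L
  end_m <- m + 2L
  end_y <- y + (end_m > 12L)
  end_m <- ((end_m - 1L) %% 12L) + 1L
  last <- as.Date(sprintf("%d-%02d-01", end_y, end_m)) + .month_days(end_m) - 1L
  seq(issue_date, last, by = "day")
}

#' @export
print.ensemble_forecast <- function(x, ...) {
  cat("<ensemble_forecast>", x$site_id, "issued", format(x$issue_date),
      sprintf("lead %d, %d members, skill_rho = %.2f\n",
              x$lead, x$n_members, x$skill_rho))
  cat("  member totals (mm): ",
      paste(round(quantile(x$totals, c(0, .25, .5, .75, 1)), 1),
            collapse = " / "), "\n")
  invisible(x)
}
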