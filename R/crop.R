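#' Soil profile for the water-bucket crop proxy
#'
#' @param label soil label, e.g. `"Dalby, high"`.
#' @param pawc plant available water capacity, mm (> 0).
#' @param runoff_frac fraction of rain above the intensity threshold lost to
#'   surface runoff.
#' @param evap_coeff soil evaporation scale, mm day-1 at a full bare bucket.
#' @return a `soil_profile` list.
#' @export
soil_profile <- function(label, pawc, runoff_frac = 0.5, evap_coeff = 4) {
  .assert(pawc > 0, "PAWC must be > 0", "cropval_parameter_error")
  .assert(runoff_frac >= 0 && runoff_frac <= 1,
          "runoff_frac must be in [0, 1]", "cropval_parameter_error")
  structure(list(label = label, pawc = pawc, runoff_frac = runoff_frac,
                 evap_coeff = evap_coeff), class = "soil_profile")
}

#' Soil presets for the four study locations
#'
#' Published PAW/PAWC pairs for the high/medium/low soils at Capella, Dalby,
#' Goondiwindi and Moree. The two columns are internally inconsistent for
#' some soils (e.g. Moree high lists PAW 299 above PAWC 254); both are
#' reported verbatim and only PAWC is used by the proxy.
#' @return data.table `site, depth_class, soil_type, paw, pawc`.
#' @export
soil_presets <- function() {
  data.table(
    site = rep(c("Capella", "Dalby", "Goondiwindi", "Moree"), each = 3),
    depth_class = rep(c("high", "medium", "low"), 4),
    soil_type = c("Black clay Vertosol", "Grey medium clay Vertosol",
                  "Black light clay Vertosol",
                  "Black clay Vertosol", "Black medium clay Vertosol",
                  "Grey light clay Vertosol",
                  "Grey clay Vertosol", "Grey medium clay Vertosol",
                  "Grey light clay Vertosol",
                  "Black clay Vertosol", "Grey medium clay Vertosol",
                  "Black light clay Vertosol"),
    paw = c(287, 189, 146, 308, 253, 175, 283, 214, 179, 299, 220, 106),
    pawc = c(415, 274, 146, 400, 344, 274, 313, 361, 310, 254, 304, 124)
  )
}

#' Factor levels of the crop design (G x M) space
#' @return named list of the default factor levels.
#' @export
design_levels <- function() {
  list(maturity = c("early", "medium", "late"),
       tillering = c("none", "medium", "high"),
       density = c(3.5, 5, 6.5, 8),
       row_config = c("solid", "single_skip"),
       n_rate = c(50, 100, 150))
}

#' A crop design: one genotype x management combination
#'
#' @param maturity one of early/medium/late.
#' @param tillering one of none/medium/high.
#' @param density plants m-2.
#' @param row_config `"solid"` (1 m rows) or `"single_skip"`.
#' @param n_rate nitrogen applied at sowing, kg N ha-1.
#' @param levels admissible factor levels (default [design_levels()]).
#' @return a `crop_design` list.
#' @export
crop_design <- function(maturity = "medium", tillering = "medium",
                        density = 5, row_config = "solid", n_rate = 50,
                        levels = design_levels()) {
  .assert(maturity %in% levels$maturity, "invalid maturity",
          "cropval_parameter_error")
  .assert(tillering %in% levels$tillering, "invalid tillering",
          "cropval_parameter_error")
  .assert(density %in% levels$density, "invalid density",
          "cropval_parameter_error")
  .assert(row_config %in% levels$row_config, "invalid row_config",
          "cropval_parameter_error")
  .assert(n_rate %in% levels$n_rate, "invalid n_rate",
          "cropval_parameter_error")
  structure(list(maturity = maturity, tillering = tillering,
                 density = density, row_config = row_config,
                 n_rate = n_rate), class = "crop_design")
}

#' The environmental context of a simulation
#'
#' @param site_id site label.
#' @param soil a [soil_profile()].
#' @param isw_frac initial soil water at sowing as a fraction of PAWC, in
#'   (0, 1].
#' @param sowing_month sowing window start month (9--12 or 1; sowing happens
#'   on the first of the month, the forecast issue date).
#' @return a `crop_environment` list.
#' @export
crop_environment <- function(site_id, soil, isw_frac = 0.6,
                             sowing_month = 10L) {
  .assert(inherits(soil, "soil_profile"), "soil must be a soil_profile",
          "cropval_parameter_error")
  .assert(isw_frac > 0 && isw_frac <= 1, "isw_frac must be in (0, 1]",
          "cropval_parameter_error")
  structure(list(site_id = site_id, soil = soil, isw_frac = isw_frac,
                 sowing_month = as.integer(sowing_month)),
            class = "crop_environment")
}

#' Parameters of the water-bucket sorghum proxy
#'
#' All behavioural constants of the proxy in one declared block. Thermal
#' time drives phenology (base 11 degC; maturity at the class target, full
#' canopy at `tt_cover_frac` of it); biomass is transpiration efficiency
#' times cumulative transpiration, capped by a Michaelis-type nitrogen
#' ceiling; yield is harvest index times capped biomass, bounded by the
#' potential.
#'
#' @param t_base base temperature, degC.
#' @param tt_targets named thermal-time targets to maturity (degCd) for
#'   early/medium/late.
#' @param tt_cover_frac fraction of the target at which canopy closes.
#' @param d0 transpiration demand at full canopy and reference density,
#'   mm day-1.
#' @param dens_ref,dens_exp reference plant density and the exponent of the
#'   density demand response.
#' @param till_mult named demand multipliers for none/medium/high tillering.
#' @param row_factor_skip demand/interception factor for single-skip rows.
#' @param kl daily extractable fraction of stored soil water.
#' @param runoff_thresh rain intensity threshold above which surface runoff
#'   occurs, mm day-1.
#' @param te transpiration efficiency, t ha-1 biomass per mm transpired.
#' @param hi harvest index.
#' @param n_max,kn scale (t ha-1) and half-saturation (kg N ha-1) of the
#'   nitrogen biomass ceiling `n_max * n / (n + kn)`.
#' @param y_pot potential yield bound, t ha-1.
#' @param fail_thresh failed-crop yield threshold, t ha-1 (drives the
#'   failed/harvested cost split in the economics layer).
#' @param max_season_days hard cap on season length.
#' @return a `proxy_params` list.
#' @export
proxy_params <- function(t_base = 11,
                         tt_targets = c(early = 1500, medium = 1700,
                                        late = 1900),
                         tt_cover_frac = 0.4,
                         d0 = 7, dens_ref = 5, dens_exp = 0.35,
                         till_mult = c(none = 0.85, medium = 1, high = 1.15),
                         row_factor_skip = 0.8,
                         kl = 0.08, runoff_thresh = 30,
                         te = 0.018, hi = 0.45,
                         n_max = 18, kn = 60,
                         y_pot = 12, fail_thresh = 0.2,
                         max_season_days = 220L) {
  .assert(all(tt_targets > 0) && te > 0 && hi > 0 && y_pot > 0,
          "proxy parameters must be positive", "cropval_parameter_error")
  structure(as.list(environment()), class = "proxy_params")
}

.pp_vector <- function(pp, tt_target, ...) {
  c(pp$t_base, pp$tt_cover_frac, pp$d0, pp$dens_ref, pp$dens_exp, pp$kl,
    pp$runoff_thresh, pp$te, pp$hi, pp$n_max, pp$kn, pp$y_pot,
    pp$fail_thresh)
}

# one combo row for the C++ batch kernel
.combo_row <- function(env, design, pp) {
  c(pawc = env$soil$pawc, isw = env$isw_frac,
    runoff_frac = env$soil$runoff_frac, evap_coeff = env$soil$evap_coeff,
    tt_target = unname(pp$tt_targets[[design$maturity]]),
    till = unname(pp$till_mult[[design$tillering]]),
    density = design$density,
    row_factor = if (design$row_config == "single_skip")
      pp$row_factor_skip else 1,
    n_rate = design$n_rate)
}

#' Simulate one crop with the water-bucket proxy
#'
#' Daily soil-water bucket from sowing (the first day of the environment's
#' sowing month in `year`) to thermal maturity:
#' `SW <- clamp(SW + rain - runoff - soil_evap - transpiration, 0, PAWC)`
#' (bucket overflow is counted as runoff/drainage). Biomass is
#' transpiration efficiency times cumulative transpiration, capped by the
#' nitrogen ceiling; yield is harvest index times capped biomass, bounded at
#' the potential; the crop is flagged failed below the failure threshold.
#' Deterministic for a given weather series.
#'
#' @param weather daily weather covering sowing through maturity.
#' @param env a [crop_environment()].
#' @param design a [crop_design()].
#' @param year sowing calendar year.
#' @param params a [proxy_params()].
#' @param trace_id trace identifier recorded in the output (0 = observed).
#' @return a one-row `yield_record` data.table: `site, soil, isw, window,
#'   maturity, tillering, density, row_config, n_rate, year, trace, yield,
#'   failed`, with a `water_balance` attribute holding the season sums
#'   (rain, runoff, soil_evap, transpiration, initial/final soil water).
#' @export
simulate_crop <- function(weather, env, design, year,
                          params = proxy_params(), trace_id = 0L) {
  sow <- as.Date(sprintf("%d-%02d-01", year, env$sowing_month))
  i0 <- match(sow, weather$date)
  .assert(!is.na(i0), "weather does not cover the sowing date",
          "cropval_coverage_error")
  i1 <- min(nrow(weather), i0 + params$max_season_days - 1L)
  idx <- i0:i1
  combos <- matrix(.combo_row(env, design, params), nrow = 1)
  res <- simulate_crop_batch_cpp(
    matrix(weather$rain[idx], ncol = 1), matrix(weather$maxt[idx], ncol = 1),
    matrix(weather$mint[idx], ncol = 1), combos, .pp_vector(params))
  # the weather must not run out before the season can complete: maturity
  # unreached with fewer days available than the season cap means the series
  # ended mid-crop (at the cap the season is truncated by design)
  if (res$mature[1, 1] == 0 && length(idx) < params$max_season_days) {
    stop(errorCondition("weather ends before crop maturity",
                        class = c("cropval_coverage_error", "cropval_error")))
  }
  out <- data.table(
    site = env$site_id, soil = env$soil$label, isw = env$isw_frac,
    window = env$sowing_month, maturity = design$maturity,
    tillering = design$tillering, density = design$density,
    row_config = design$row_config, n_rate = design$n_rate,
    year = as.integer(year), trace = as.integer(trace_id),
    yield = res$yield[1, 1], failed = res$failed[1, 1] == 1
  )
  setattr(out, "water_balance", c(
    rain = res$rain[1, 1], runoff = res$runoff[1, 1],
    soil_evap = res$soil_evap[1, 1], transpiration = res$transpiration[1, 1],
    initial_sw = env$isw_frac * env$soil$pawc, final_sw = res$final_sw[1, 1],
    days = res$days[1, 1]))
  out[]
}

#' Simulate a factorial of environments and designs over weather traces
#'
#' One yield record per (environment, design, year, trace). Weather traces
#' are supplied as a named list (`"0"` = observed weather; other names are
#' trace ids) of daily weather tables; each must cover every season.
#'
#' @param weather_traces named list of daily weather tables.
#' @param envs list of [crop_environment()]s.
#' @param designs list of [crop_design()]s.
#' @param years sowing years to simulate.
#' @param params a [proxy_params()].
#' @return a `yield_record` data.table (see [simulate_crop()]), one row per
#'   combination; order-invariant content.
#' @export
simulate_factorial <- function(weather_traces, envs, designs, years,
                               params = proxy_params()) {
  if (inherits(envs, "crop_environment")) envs <- list(envs)
  if (inherits(designs, "crop_design")) designs <- list(designs)
  out <- list()
  for (tr in names(weather_traces)) {
    w <- weather_traces[[tr]]
    for (env in envs) {
      for (design in designs) {
        for (yr in years) {
          out[[length(out) + 1L]] <-
            simulate_crop(w, env, design, yr, params,
                          trace_id = as.integer(tr))
        }
      }
    }
  }
  rbindlist(out)
}

# fast path used by the pipeline: one C++ call over all (env, design)
# combos and traces for a single (window, year) weather block
.simulate_block <- function(rain_m, maxt_m, mint_m, combo_meta, params) {
  res <- simulate_crop_batch_cpp(rain_m, maxt_m, mint_m,
                                 as.matrix(combo_meta$combos),
                                 .pp_vector(params))
  n_tr <- ncol(rain_m)
  meta <- combo_meta$meta
  out <- meta[rep(seq_len(nrow(meta)), n_tr)]
  out[, trace := rep(as.integer(colnames(rain_m)), each = nrow(meta))]
  out[, yield := as.vector(res$yield)]
  out[, failed := as.vector(res$failed) == 1]
  out[]
}
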