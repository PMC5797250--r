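#' Build and validate an experiment configuration
#'
#' One plain (YAML-serializable) list driving the whole experiment:
#' climate parameters per site, soils, factor levels, hindcast span,
#' ensemble size, skill, economics, seeds.
#'
#' @param sites named list; each site a list with `annual_rain_mean`,
#'   `summer_fraction`, `teleconnection_strength` and a named `soils` list
#'   of PAWC values (mm).
#' @param start_year,n_years hindcast span (sowing years).
#' @param enso_ar1 index persistence.
#' @param windows sowing/issue window start months.
#' @param isw_levels initial soil water fractions simulated.
#' @param maturities,tillering,densities,row_configs,n_rates design factor
#'   levels.
#' @param n_members ensemble members per issue.
#' @param skill_rho ensemble skill parameter.
#' @param value_window,value_isw the decision environment (sowing month and
#'   ISW) used by the value layer.
#' @param farmer farmer-practice design (named list).
#' @param econ economic parameters (named list, see [econ_params()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(
    sites = list(Dalby = list(annual_rain_mean = 670, summer_fraction = 0.64,
                              teleconnection_strength = 0.35,
                              soils = list(high = 400, medium = 344,
                                           low = 274))),
    start_year = 1981L, n_years = 35L,
    enso_ar1 = 0.8,
    windows = c(9L, 10L, 11L, 12L, 1L),
    isw_levels = c(0.2, 0.6),
    maturities = c("early", "medium"),
    tillering = c("none", "medium"),
    densities = c(5, 8),
    row_configs = c("solid", "single_skip"),
    n_rates = c(50, 150),
    n_members = 33L,
    skill_rho = 0.5,
    value_window = 10L, value_isw = 0.6,
    farmer = list(maturity = "medium", tillering = "medium", density = 5,
                  row_config = "solid", n_rate = 50),
    econ = list(price = 254, insurance_rate = 0.01, cost_failed = 161,
                cost_harvested = 211, urea_price = 0.30,
                urea_n_fraction = 0.46, n_base = 50, dsr_threshold = 600),
    seed = 1L) {
  cfg <- list(sites = sites, start_year = as.integer(start_year),
              n_years = as.integer(n_years), enso_ar1 = enso_ar1,
              windows = as.integer(windows), isw_levels = isw_levels,
              maturities = maturities, tillering = tillering,
              densities = densities, row_configs = row_configs,
              n_rates = n_rates, n_members = as.integer(n_members),
              skill_rho = skill_rho,
              value_window = as.integer(value_window),
              value_isw = value_isw, farmer = farmer, econ = econ,
              seed = as.integer(seed))
  validate_experiment_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' Validate an experiment configuration against the schema
#' @param cfg a configuration list.
#' @return `cfg` invisibly; `cropval_config_error` on violation.
#' @export
validate_experiment_config <- function(cfg) {
  need <- c("sites", "start_year", "n_years", "enso_ar1", "windows",
            "isw_levels", "maturities", "tillering", "densities",
            "row_configs", "n_rates", "n_members", "skill_rho",
            "value_window", "value_isw", "farmer", "econ", "seed")
  .assert(all(need %in% names(cfg)),
          paste("config missing:",
                paste(setdiff(need, names(cfg)), collapse = ", ")),
          "cropval_config_error")
  .assert(length(cfg$sites) >= 1 &&
            all(vapply(cfg$sites, function(s)
              all(c("annual_rain_mean", "soils") %in% names(s)),
              logical(1))),
          "each site needs annual_rain_mean and soils",
          "cropval_config_error")
  .assert(cfg$n_years >= 3, "need >= 3 hindcast years",
          "cropval_config_error")
  .assert(abs(cfg$enso_ar1) < 1, "|enso_ar1| must be < 1",
          "cropval_config_error")
  .assert(cfg$skill_rho >= 0 && cfg$skill_rho <= 1,
          "skill_rho must be in [0, 1]", "cropval_config_error")
  .assert(all(cfg$windows %in% c(9L, 10L, 11L, 12L, 1L)),
          "windows must be Sep-Jan months", "cropval_config_error")
  .assert(cfg$value_window %in% cfg$windows,
          "value_window must be one of windows", "cropval_config_error")
  .assert(cfg$value_isw %in% cfg$isw_levels,
          "value_isw must be one of isw_levels", "cropval_config_error")
  lv <- list(maturities = design_levels()$maturity,
             tillering = design_levels()$tillering,
             densities = design_levels()$density,
             row_configs = design_levels()$row_config,
             n_rates = design_levels()$n_rate)
  for (nm in names(lv)) {
    .assert(all(cfg[[nm]] %in% lv[[nm]]),
            paste("invalid", nm), "cropval_config_error")
  }
  .assert(cfg$farmer$maturity %in% cfg$maturities &&
            cfg$farmer$tillering %in% cfg$tillering &&
            cfg$farmer$density %in% cfg$densities &&
            cfg$farmer$row_config %in% cfg$row_configs &&
            cfg$farmer$n_rate %in% cfg$n_rates,
          "farmer design must lie inside the configured factor levels",
          "cropval_config_error")
  invisible(cfg)
}

#' Reduced desk-scale experiment configuration
#'
#' One site, three soils, five sowing windows, two levels each of initial
#' soil water, density, nitrogen, maturity, tillering and row
#' configuration, 35 hindcast years, 33 ensemble members:
#' 3 x 5 x 2^6 x 35 x 34 = 1,142,400 crop-year simulations.
#' @param skill_rho ensemble skill parameter.
#' @param seed master seed.
#' @param teleconnection_strength rainfall teleconnection of the site.
#' @return an `experiment_config`.
#' @export
reduced_experiment_config <- function(skill_rho = 0.5, seed = 1L,
                                      teleconnection_strength = 0.35) {
  cfg <- experiment_config(skill_rho = skill_rho, seed = seed)
  cfg$sites$Dalby$teleconnection_strength <- teleconnection_strength
  cfg
}

#' Serialize / parse a configuration as YAML
#' @param cfg an `experiment_config`.
#' @param path file path.
#' @return `write_experiment_config` returns `path`;
#'   `read_experiment_config` the parsed, validated config.
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$start_year <- as.integer(cfg$start_year)
  cfg$n_years <- as.integer(cfg$n_years)
  cfg$windows <- as.integer(cfg$windows)
  cfg$n_members <- as.integer(cfg$n_members)
  cfg$value_window <- as.integer(cfg$value_window)
  cfg$seed <- as.integer(cfg$seed)
  validate_experiment_config(cfg)
  structure(cfg, class = "experiment_config")
}

# order-sensitive checksum of the serialized config (manifest provenance)
.config_hash <- function(cfg) {
  raw <- as.integer(serialize(unclass(cfg), NULL, ascii = TRUE))
  sprintf("%08x", sum(raw * (seq_along(raw) %% 997)) %% 2^31)
}

.site_params <- function(cfg, site_name, seed_offset = 0L) {
  s <- cfg$sites[[site_name]]
  climate_params(
    annual_rain_mean = s$annual_rain_mean,
    summer_fraction = s$summer_fraction %||% 0.64,
    teleconnection_strength = s$teleconnection_strength %||% 0.3,
    seed = cfg$seed + seed_offset, site_id = site_name)
}

# issue year for window month: Sep-Dec sow in the hindcast year itself,
# January in the following calendar year
.issue_year <- function(hindcast_year, window) {
  hindcast_year + (window < 9L)
}

.issue_seed <- function(cfg, window, hindcast_year) {
  (cfg$seed + window * 13L +
     (hindcast_year - cfg$start_year) * 307L + 101L) %% .Machine$integer.max
}

# ---- stages ------------------------------------------------------------

.synth_stage <- function(cfg) {
  n_gen <- cfg$n_years + 1L   # pad one year so late seasons complete
  enso <- generate_enso_index(cfg$enso_ar1, n_gen, seed = cfg$seed,
                              start_year = cfg$start_year)
  weather <- list()
  for (i in seq_along(cfg$sites)) {
    nm <- names(cfg$sites)[i]
    params <- .site_params(cfg, nm, seed_offset = i)
    weather[[nm]] <- generate_daily_weather(params, n_gen, enso,
                                            start_year = cfg$start_year)
  }
  list(enso = enso, weather = weather)
}

.forecast_stage <- function(cfg, synth) {
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  ens <- list()
  for (nm in names(cfg$sites)) {
    obs <- synth$weather[[nm]]
    params <- .site_params(cfg, nm)
    for (w in cfg$windows) {
      tot_w <- window_totals(obs, w)
      for (y in years) {
        iy <- .issue_year(y, w)
        issue <- as.Date(sprintf("%d-%02d-01", iy, w))
        key <- sprintf("%s|%d|%d", nm, w, y)
        ens[[key]] <- generate_ensemble_forecast(
          obs, issue, cfg$skill_rho, n_members = cfg$n_members,
          params = params, seed = .issue_seed(cfg, w, y),
          totals_by_year = tot_w)
      }
    }
  }
  # analogue (phase) system hindcast over the same windows
  analogue <- lapply(names(cfg$sites), function(nm) {
    a <- analogue_hindcast(synth$weather[[nm]], synth$enso,
                           months = cfg$windows)
    a[, site := nm]
    a
  })
  list(ensembles = ens, analogue = rbindlist(analogue))
}

.config_designs <- function(cfg) {
  g <- expand.grid(n_rate = cfg$n_rates, density = cfg$densities,
                   maturity = cfg$maturities, tillering = cfg$tillering,
                   row_config = cfg$row_configs,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  as.data.table(g)[, .(maturity, tillering, density, row_config, n_rate)]
}

# combos matrix + metadata for one site (all soils x isw x designs)
.config_combos <- function(cfg, site_name, pp) {
  soils <- cfg$sites[[site_name]]$soils
  designs <- .config_designs(cfg)
  rows <- list(); mats <- list()
  for (sl in names(soils)) {
    soil <- soil_profile(paste0(site_name, ", ", sl), soils[[sl]])
    for (isw in cfg$isw_levels) {
      meta <- copy(designs)
      meta[, `:=`(site = site_name, soil = sl, isw = isw)]
      mat <- t(vapply(seq_len(nrow(designs)), function(i) {
        d <- designs[i]
        c(soil$pawc, isw, soil$runoff_frac, soil$evap_coeff,
          unname(pp$tt_targets[[d$maturity]]),
          unname(pp$till_mult[[d$tillering]]),
          d$density,
          if (d$row_config == "single_skip") pp$row_factor_skip else 1,
          d$n_rate)
      }, numeric(9)))
      rows[[length(rows) + 1L]] <- meta
      mats[[length(mats) + 1L]] <- mat
    }
  }
  list(meta = rbindlist(rows), combos = do.call(rbind, mats))
}

.simulate_stage <- function(cfg, synth, ensembles, pp = proxy_params()) {
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  out <- list()
  for (nm in names(cfg$sites)) {
    obs <- synth$weather[[nm]]
    cm <- .config_combos(cfg, nm, pp)
    for (w in cfg$windows) {
      meta_w <- copy(cm$meta)[, window := w]
      for (y in years) {
        iy <- .issue_year(y, w)
        sow <- as.Date(sprintf("%d-%02d-01", iy, w))
        ens <- ensembles[[sprintf("%s|%d|%d", nm, w, y)]]
        .assert(!is.null(ens),
                sprintf("missing ensemble for %s window %d year %d",
                        nm, w, y), "cropval_dependency_error")
        i0 <- match(sow, obs$date)
        .assert(!is.na(i0) && i0 + pp$max_season_days - 1L <= nrow(obs),
                "weather does not cover the season",
                "cropval_coverage_error")
        idx <- i0:(i0 + pp$max_season_days - 1L)
        n_m <- ens$n_members
        nd <- nrow(ens$members) / n_m
        rain_m <- matrix(obs$rain[idx], length(idx), n_m + 1L)
        maxt_m <- matrix(obs$maxt[idx], length(idx), n_m + 1L)
        mint_m <- matrix(obs$mint[idx], length(idx), n_m + 1L)
        rain_m[seq_len(nd), -1L] <- matrix(ens$members$rain, nd)
        maxt_m[seq_len(nd), -1L] <- matrix(ens$members$maxt, nd)
        mint_m[seq_len(nd), -1L] <- matrix(ens$members$mint, nd)
        # beyond the forecast window the member seasons see climatological
        # (fresh synthetic) weather, not the realized tail -- otherwise a
        # zero-skill ensemble would still carry real information about the
        # season. At skill 1 the conditional distribution is degenerate at
        # the observation, so the observed tail stands.
        if (cfg$skill_rho < 1 && nd < length(idx)) {
          tail_i <- (nd + 1L):length(idx)
          set.seed((.issue_seed(cfg, w, y) + 7L) %% .Machine$integer.max)
          tails <- .daily_core(rep(obs$date[idx][tail_i], n_m),
                               .site_params(cfg, nm),
                               mult = rep(1, length(tail_i) * n_m))
          rain_m[tail_i, -1L] <- matrix(tails$rain, length(tail_i))
          maxt_m[tail_i, -1L] <- matrix(tails$maxt, length(tail_i))
          mint_m[tail_i, -1L] <- matrix(tails$mint, length(tail_i))
        }
        colnames(rain_m) <- c("0", seq_len(n_m))
        blk <- .simulate_block(rain_m, maxt_m, mint_m,
                               list(meta = meta_w, combos = cm$combos), pp)
        blk[, year := y]
        out[[length(out) + 1L]] <- blk
      }
    }
  }
  yields <- rbindlist(out)
  setcolorder(yields, c("site", "soil", "isw", "window", "maturity",
                        "tillering", "density", "row_config", "n_rate",
                        "year", "trace", "yield", "failed"))
  yields[]
}

.rain_verification <- function(cfg, synth, ensembles) {
  rows <- list()
  for (nm in names(cfg$sites)) {
    obs <- synth$weather[[nm]]
    years <- cfg$start_year + seq_len(cfg$n_years) - 1L
    for (w in cfg$windows) {
      tot <- window_totals(obs, w)
      iy <- .issue_year(years, w)
      keep <- as.character(iy) %in% names(tot)
      cl_tot <- tot[as.character(iy[keep])]
      ev_a <- event_from_reference(cl_tot, "above_median")
      ev_1 <- event_from_reference(cl_tot, "tercile_1")
      ev_3 <- event_from_reference(cl_tot, "tercile_3")
      for (j in which(keep)) {
        y <- years[j]
        ens <- ensembles[[sprintf("%s|%d|%d", nm, w, y)]]
        o <- tot[[as.character(iy[j])]]
        sd_ <- shift_dispersion(ens$totals, unname(cl_tot))
        rows[[length(rows) + 1L]] <- data.table(
          site = nm, window = w, year = y,
          p_above = forecast_probability(ens$totals, ev_a),
          p_t1 = forecast_probability(ens$totals, ev_1),
          p_t3 = forecast_probability(ens$totals, ev_3),
          outcome_above = .event_indicator(o, ev_a),
          outcome_t1 = .event_indicator(o, ev_1),
          outcome_t3 = .event_indicator(o, ev_3),
          amd = sd_$AMD, vr = sd_$VR)
      }
    }
  }
  rbindlist(rows)
}

.value_stage <- function(cfg, yields, skill_table = NULL) {
  econ <- do.call(econ_params, cfg$econ)
  farmer_design <- do.call(crop_design, cfg$farmer)
  reports <- list()
  for (nm in names(cfg$sites)) {
    for (sl in names(cfg$sites[[nm]]$soils)) {
      rec <- yields[site == nm & soil == sl &
                      window == cfg$value_window & isw == cfg$value_isw]
      .assert(nrow(rec) > 0, "no records for the value environment",
              "cropval_dependency_error")
      st <- if (!is.null(skill_table)) {
        skill_table[site == nm & soil == sl &
                      window == cfg$value_window & isw == cfg$value_isw]
      } else NULL
      fp <- farmer_profile(rec, farmer_design, econ)
      so <- optimize_static(rec, econ)
      fo <- select_forecast_designs(rec, econ, skill_table = st)
      pk <- perfect_knowledge(rec, econ)
      reports[[paste(nm, sl, sep = "_")]] <-
        value_report(fp, so, fo, pk, site = nm, soil = sl)
    }
  }
  reports
}

#' Run the reduced experiment end to end in memory
#'
#' Synthesizes the index and weather, issues tunable-skill ensemble
#' hindcasts for every window and year, runs the analogue system, simulates
#' the crop factorial over observed and member weather, verifies rainfall
#' and yield events, and prices the four design strategies per soil.
#'
#' @param config an [experiment_config()]; default
#'   [reduced_experiment_config()].
#' @param skill_rho optional override of the configured skill.
#' @param seed optional override of the configured master seed.
#' @param events yield event kinds to verify (default above/below median,
#'   the event the design filter uses).
#' @return list with `config`, `enso`, `weather`, `analogue` (phase-system
#'   hindcast table), `rain_verification`, `yields`, `yield_skill`,
#'   `value_reports`, `value_table`.
#' @export
run_reduced_experiment <- function(config = reduced_experiment_config(),
                                   skill_rho = NULL, seed = NULL,
                                   events = "above_median") {
  cfg <- config
  if (!is.null(skill_rho)) cfg$skill_rho <- skill_rho
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_experiment_config(cfg)
  synth <- .synth_stage(cfg)
  fc <- .forecast_stage(cfg, synth)
  yields <- .simulate_stage(cfg, synth, fc$ensembles)
  skill <- yield_event_skill(yields, events = events)
  rainv <- .rain_verification(cfg, synth, fc$ensembles)
  reports <- .value_stage(cfg, yields, skill_table = skill)
  list(config = cfg, enso = synth$enso, weather = synth$weather,
       analogue = fc$analogue, rain_verification = rainv,
       yields = yields, yield_skill = skill, value_reports = reports,
       value_table = value_report_table(reports))
}

# ---- stage-wise CSV pipeline -------------------------------------------

.stage_order <- c("synth", "forecast", "simulate", "verify", "value")

.manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

.read_manifest <- function(out_dir) {
  p <- .manifest_path(out_dir)
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

.register <- function(manifest, stage, files, out_dir) {
  for (f in files) {
    manifest$files[[f]] <- list(stage = stage,
                                rows = .csv_rows(file.path(out_dir, f)))
  }
  manifest$stages <- union(manifest$stages, stage)
  manifest
}

.check_artifact <- function(manifest, file, out_dir, needed_by) {
  path <- file.path(out_dir, file)
  .assert(file.exists(path),
          sprintf("stage '%s' requires artifact '%s' from an earlier stage",
                  needed_by, file), "cropval_dependency_error")
  expect <- manifest$files[[file]]$rows
  if (!is.null(expect)) {
    .assert(.csv_rows(path) == expect,
            sprintf("artifact '%s' row count differs from manifest (stage '%s')",
                    file, needed_by), "cropval_dependency_error")
  }
  path
}

#' Run the experiment pipeline stage-wise, writing CSV artifacts
#'
#' Stages (in dependency order): `synth` (index + weather), `forecast`
#' (ensemble archives + analogue table), `simulate` (yield table),
#' `verify` (yield-event verification table), `value` (value reports and
#' strategy log). Each stage reads its upstream artifacts from `out_dir`
#' when not computed in the same invocation and fails with a
#' `cropval_dependency_error` naming the missing/tampered artifact
#' otherwise. Re-running with identical config and seed reproduces
#' byte-identical CSV payloads.
#'
#' @param config an [experiment_config()].
#' @param stages subset of the five stages to run.
#' @param out_dir output directory (created if needed).
#' @return the run manifest (list: config hash, seed, stages, files with
#'   row counts), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config, stages = .stage_order, out_dir) {
  validate_experiment_config(config)
  .assert(all(stages %in% .stage_order),
          paste("unknown stage:",
                paste(setdiff(stages, .stage_order), collapse = ", ")),
          "cropval_config_error")
  stages <- .stage_order[.stage_order %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  manifest <- .read_manifest(out_dir) %||%
    list(config_hash = hash, seed = config$seed, stages = character(),
         files = list())
  manifest$config_hash <- hash
  manifest$seed <- config$seed
  hdr <- c(paste("config_hash:", hash), paste("seed:", config$seed))
  pp <- proxy_params()

  synth <- NULL; ensembles <- NULL; yields <- NULL; skill <- NULL

  load_synth <- function() {
    if (!is.null(synth)) return(synth)
    w <- list()
    for (nm in names(config$sites)) {
      f <- sprintf("weather_%s.csv", nm)
      w[[nm]] <- read_weather_csv(
        .check_artifact(manifest, f, out_dir, "downstream"), site_id = nm)
    }
    ep <- read_table_csv(
      .check_artifact(manifest, "enso_index.csv", out_dir, "downstream"))
    setattr(ep, "class", c("enso_index", class(data.table())))
    setattr(ep, "ar1_coeff", config$enso_ar1)
    synth <<- list(enso = ep, weather = w)
    synth
  }

  if ("synth" %in% stages) {
    synth <- .synth_stage(config)
    files <- "enso_index.csv"
    write_table_csv(synth$enso, file.path(out_dir, "enso_index.csv"), hdr)
    for (nm in names(synth$weather)) {
      f <- sprintf("weather_%s.csv", nm)
      write_weather_csv(synth$weather[[nm]], file.path(out_dir, f), hdr)
      files <- c(files, f)
    }
    manifest <- .register(manifest, "synth", files, out_dir)
  }

  if ("forecast" %in% stages) {
    fc <- .forecast_stage(config, load_synth())
    ensembles <- fc$ensembles
    dir.create(file.path(out_dir, "ensembles"), showWarnings = FALSE)
    idx <- list(); files <- character()
    for (key in names(ensembles)) {
      ens <- ensembles[[key]]
      f <- file.path("ensembles",
                     sprintf("%s_%s.csv", ens$site_id,
                             format(ens$issue_date, "%Y%m")))
      write_ensemble_csv(ens, file.path(out_dir, f), hdr)
      idx[[length(idx) + 1L]] <- data.table(
        issue_key = key, site = ens$site_id,
        issue_date = format(ens$issue_date),
        skill_rho = ens$skill_rho, n_members = ens$n_members, file = f)
      files <- c(files, f)
    }
    write_table_csv(rbindlist(idx),
                    file.path(out_dir, "ensemble_index.csv"), hdr)
    write_table_csv(fc$analogue,
                    file.path(out_dir, "analogue_forecasts.csv"), hdr)
    write_table_csv(soi_phase_table(load_synth()$enso),
                    file.path(out_dir, "phase_table.csv"), hdr)
    manifest <- .register(manifest, "forecast",
                          c(files, "ensemble_index.csv",
                            "analogue_forecasts.csv", "phase_table.csv"),
                          out_dir)
  }

  load_ensembles <- function() {
    if (!is.null(ensembles)) return(ensembles)
    idx <- read_table_csv(
      .check_artifact(manifest, "ensemble_index.csv", out_dir, "simulate"))
    out <- list()
    for (i in seq_len(nrow(idx))) {
      mem <- read_table_csv(
        .check_artifact(manifest, idx$file[i], out_dir, "simulate"))
      mem[, date := as.Date(date)]
      out[[idx$issue_key[i]]] <- list(
        site_id = idx$site[i], issue_date = as.Date(idx$issue_date[i]),
        skill_rho = idx$skill_rho[i], n_members = idx$n_members[i],
        members = mem,
        totals = mem[, .(t = sum(rain)), by = member]$t)
    }
    ensembles <<- out
    out
  }

  if ("simulate" %in% stages) {
    yields <- .simulate_stage(config, load_synth(), load_ensembles(), pp)
    write_table_csv(yields, file.path(out_dir, "yields.csv"), hdr)
    manifest <- .register(manifest, "simulate", "yields.csv", out_dir)
  }

  load_yields <- function(stage) {
    if (!is.null(yields)) return(yields)
    y <- read_table_csv(
      .check_artifact(manifest, "yields.csv", out_dir, stage))
    y[, failed := as.logical(failed)]
    yields <<- y
    y
  }

  if ("verify" %in% stages) {
    skill <- yield_event_skill(load_yields("verify"),
                               events = "above_median")
    write_table_csv(skill, file.path(out_dir, "verification.csv"), hdr)
    rainv <- .rain_verification(config, load_synth(), load_ensembles())
    write_table_csv(rainv, file.path(out_dir, "rain_verification.csv"), hdr)
    manifest <- .register(manifest, "verify",
                          c("verification.csv", "rain_verification.csv"),
                          out_dir)
  }

  if ("value" %in% stages) {
    if (is.null(skill) && file.exists(file.path(out_dir,
                                                "verification.csv"))) {
      skill <- read_table_csv(
        .check_artifact(manifest, "verification.csv", out_dir, "value"))
    }
    reports <- .value_stage(config, load_yields("value"),
                            skill_table = skill)
    write_table_csv(value_report_table(reports),
                    file.path(out_dir, "value_reports.csv"), hdr)
    log_ <- rbindlist(lapply(reports, function(r) {
      rbindlist(lapply(c("farmer", "static_optimal", "forecast_optimal",
                         "perfect_knowledge"), function(s) {
        p <- r[[s]]
        data.table(site = r$site, soil = r$soil, year = p$years,
                   strategy = p$strategy,
                   design_id = unname(p$design_by_year),
                   realized_profit = unname(p$profits))
      }))
    }))
    write_table_csv(log_, file.path(out_dir, "strategy_log.csv"), hdr)
    manifest <- .register(manifest, "value",
                          c("value_reports.csv", "strategy_log.csv"),
                          out_dir)
  }

  jsonlite::write_json(manifest, .manifest_path(out_dir),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
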