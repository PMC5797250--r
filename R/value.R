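#' Economic parameters
#'
#' Grain price, insurance, fixed variable costs for failed vs harvested
#' crops, the incremental urea cost of nitrogen above the base rate, and
#' the downside-risk profit threshold. The fixed 161/211 AU$ ha-1 costs are
#' treated as the non-nitrogen, non-insurance variable costs; insurance
#' (a fraction of gross income) and the urea cost of nitrogen above
#' `n_base` are added on top, which keeps the failed-crop worked case exact
#' and the nitrogen levels economically distinct.
#'
#' @param price grain price, AU$ t-1.
#' @param insurance_rate fraction of gross income.
#' @param cost_failed,cost_harvested fixed variable costs, AU$ ha-1.
#' @param urea_price AU$ per kg urea.
#' @param urea_n_fraction nitrogen mass fraction of urea.
#' @param n_base nitrogen rate already inside the fixed costs, kg N ha-1.
#' @param dsr_threshold downside-risk profit threshold, AU$ ha-1.
#' @return an `econ_params` list.
#' @export
econ_params <- function(price = 254, insurance_rate = 0.01,
                        cost_failed = 161, cost_harvested = 211,
                        urea_price = 0.30, urea_n_fraction = 0.46,
                        n_base = 50, dsr_threshold = 600) {
  .assert(all(c(price, cost_failed, cost_harvested, urea_price,
                urea_n_fraction, dsr_threshold) >= 0) &&
            insurance_rate >= 0 && insurance_rate < 1,
          "invalid economic parameters", "cropval_parameter_error")
  structure(list(price = price, insurance_rate = insurance_rate,
                 cost_failed = cost_failed, cost_harvested = cost_harvested,
                 urea_price = urea_price, urea_n_fraction = urea_n_fraction,
                 n_base = n_base, dsr_threshold = dsr_threshold),
            class = "econ_params")
}

#' Annual profit of a crop
#'
#' `gross = yield * price`; profit is gross net of insurance, the fixed
#' failed/harvested variable cost, and the urea cost of nitrogen applied
#' above the base rate. Vectorized over `yield`, `failed` and `n_rate`.
#'
#' @param yield grain yield, t ha-1.
#' @param failed logical failed-crop flag.
#' @param n_rate nitrogen applied, kg N ha-1 (a [crop_design()] may be
#'   given instead).
#' @param econ an [econ_params()].
#' @return profit, AU$ ha-1.
#' @export
profit <- function(yield, failed, n_rate = 50, econ = econ_params()) {
  if (inherits(n_rate, "crop_design")) n_rate <- n_rate$n_rate
  .assert(all(yield >= 0), "yield must be >= 0", "cropval_parameter_error")
  gross <- yield * econ$price
  n_cost <- econ$urea_price * pmax(0, n_rate - econ$n_base) /
    econ$urea_n_fraction
  gross - econ$insurance_rate * gross -
    ifelse(failed, econ$cost_failed, econ$cost_harvested) - n_cost
}

#' Downside risk of a profit series
#'
#' Percentage of years with profit strictly below the threshold.
#' @param profits profit series, AU$ ha-1.
#' @param threshold AU$ ha-1 (default the 600 AU$ ha-1 consultation value).
#' @return percentage in `[0, 100]`.
#' @export
downside_risk <- function(profits, threshold = 600) {
  .assert(length(profits) >= 1, "empty profit series", "cropval_input_error")
  100 * sum(profits < threshold) / length(profits)
}

#' Count the crop-year simulations of a factorial configuration
#'
#' Product of the factor-level counts times years times traces. The full
#' study configuration (4 locations, 5 sowing windows, 3 soils, 4 initial
#' soil water levels, 2 row configurations, 4 densities, 3 N levels, 3
#' maturities, 3 tillering types, 34 years, 100 traces) gives 176,256,000.
#'
#' @param config named list with elements `locations, windows, soils, isw,
#'   row_configs, densities, n_rates, maturities, tillering` (vectors or
#'   counts), `n_years`, `n_traces`.
#' @return the crop-year count (numeric, may exceed integer range).
#' @export
count_crop_year_simulations <- function(config = study_factorial_config()) {
  fac <- config[c("locations", "windows", "soils", "isw", "row_configs",
                  "densities", "n_rates", "maturities", "tillering")]
  .assert(!any(vapply(fac, is.null, logical(1))),
          "missing factor list", "cropval_config_error")
  counts <- vapply(fac, function(x)
    if (length(x) == 1L && is.numeric(x)) as.numeric(x)
    else as.numeric(length(x)), numeric(1))
  .assert(all(counts >= 1), "empty factor list", "cropval_config_error")
  .assert(config$n_years >= 1 && config$n_traces >= 1,
          "need >= 1 year and trace", "cropval_config_error")
  prod(counts) * config$n_years * config$n_traces
}

#' The published full-factorial configuration
#' @return named list consumed by [count_crop_year_simulations()].
#' @export
study_factorial_config <- function() {
  lv <- design_levels()
  list(locations = c("Capella", "Dalby", "Goondiwindi", "Moree"),
       windows = c(9, 10, 11, 12, 1),
       soils = c("high", "medium", "low"),
       isw = c(0.2, 0.4, 0.6, 0.8),
       row_configs = lv$row_config,
       densities = lv$density,
       n_rates = lv$n_rate,
       maturities = lv$maturity,
       tillering = lv$tillering,
       n_years = 34, n_traces = 100)
}

# design identity/order helpers ------------------------------------------

.design_cols <- c("maturity", "tillering", "density", "row_config", "n_rate")

.design_id <- function(dt) {
  do.call(paste, c(as.list(dt[, .design_cols, with = FALSE]), sep = "|"))
}

# deterministic candidate ordering used for every argmax tie-break:
# lower n_rate, lower density, then listed factor order
.order_designs <- function(dt) {
  lv <- design_levels()
  order(dt$n_rate, dt$density,
        match(dt$maturity, lv$maturity),
        match(dt$tillering, lv$tillering),
        match(dt$row_config, lv$row_config))
}

# design x year profit matrices from a yield-record table (one site, soil,
# window, isw): list(obs = matrix designs x years of trace-0 profit,
# ens = matrix designs x years of ensemble-mean profit, designs, years)
.profit_matrices <- function(records, econ) {
  rec <- copy(as.data.table(records))
  rec[, profit := profit(yield, failed, n_rate, econ)]
  rec[, design_id := .design_id(rec)]
  designs <- unique(rec[, c(.design_cols, "design_id"), with = FALSE])
  designs <- designs[.order_designs(designs)]
  years <- sort(unique(rec$year))
  obs <- rec[trace == 0L]
  .assert(nrow(obs) == nrow(designs) * length(years),
          "trace-0 records must cover every design x year",
          "cropval_coverage_error")
  om <- matrix(NA_real_, nrow(designs), length(years),
               dimnames = list(designs$design_id, years))
  om[cbind(match(obs$design_id, designs$design_id),
           match(obs$year, years))] <- obs$profit
  ens <- rec[trace != 0L]
  em <- NULL
  if (nrow(ens)) {
    agg <- ens[, .(p = mean(profit)), by = .(design_id, year)]
    .assert(nrow(agg) == nrow(designs) * length(years),
            "ensemble records missing for some design x year",
            "cropval_coverage_error")
    em <- matrix(NA_real_, nrow(designs), length(years),
                 dimnames = list(designs$design_id, years))
    em[cbind(match(agg$design_id, designs$design_id),
             match(agg$year, years))] <- agg$p
  }
  list(obs = om, ens = em, designs = designs, years = years)
}

.make_profile <- function(strategy, design_by_year, profits, years, econ) {
  structure(list(strategy = strategy,
                 design_by_year = setNames(design_by_year,
                                           as.character(years)),
                 years = years,
                 profits = setNames(profits, as.character(years)),
                 mean_profit = mean(profits),
                 dsr = downside_risk(profits, econ$dsr_threshold)),
            class = "strategy_profile")
}

#' @export
print.strategy_profile <- function(x, ...) {
  cat(sprintf("<strategy_profile> %s: mean profit %.1f AU$/ha, DSR %.1f%%\n",
              x$strategy, x$mean_profit, x$dsr))
  cat("  designs used:",
      paste(unique(x$design_by_year), collapse = "; "), "\n")
  invisible(x)
}

#' Farmer-practice strategy profile
#'
#' Realized trace-0 profits of a single static design applied in every year.
#' @param records yield records for one site x soil decision environment.
#' @param design the farmer [crop_design()] (default the printed common
#'   practice: medium maturity and tillering, 5 pl m-2, solid rows,
#'   50 kg N ha-1).
#' @param econ an [econ_params()].
#' @return a `strategy_profile`.
#' @export
farmer_profile <- function(records, design = crop_design(),
                           econ = econ_params()) {
  pm <- .profit_matrices(records, econ)
  id <- paste(design$maturity, design$tillering, design$density,
              design$row_config, design$n_rate, sep = "|")
  .assert(id %in% rownames(pm$obs), "farmer design not in the records",
          "cropval_input_error")
  .make_profile("farmer", rep(id, length(pm$years)), pm$obs[id, ],
                pm$years, econ)
}

#' Static optimal design (best single design over all years)
#'
#' The design maximizing mean trace-0 profit across years; ties break by
#' lower nitrogen rate, lower density, then listed factor order. Equals
#' exhaustive search by construction.
#' @inheritParams farmer_profile
#' @return a `strategy_profile` with strategy `"static_optimal"`.
#' @export
optimize_static <- function(records, econ = econ_params()) {
  pm <- .profit_matrices(records, econ)
  .assert(nrow(pm$obs) >= 1, "empty candidate set",
          "cropval_optimization_error")
  means <- rowMeans(pm$obs)
  best <- which.max(means)   # rows already in tie-break order
  id <- rownames(pm$obs)[best]
  .make_profile("static_optimal", rep(id, length(pm$years)),
                pm$obs[best, ], pm$years, econ)
}

#' Perfect-knowledge strategy profile
#'
#' Per year, the profit-maximizing design under observed weather, realized
#' under observed weather (the hindsight optimum).
#' @inheritParams farmer_profile
#' @return a `strategy_profile` with strategy `"perfect_knowledge"`.
#' @export
perfect_knowledge <- function(records, econ = econ_params()) {
  pm <- .profit_matrices(records, econ)
  pick <- apply(pm$obs, 2L, which.max)   # first max = tie-break order
  .make_profile("perfect_knowledge", rownames(pm$obs)[pick],
                pm$obs[cbind(pick, seq_along(pm$years))], pm$years, econ)
}

#' Forecast-informed design selection (the four-step search)
#'
#' Step (i): build the design x strategy profit matrices. Step (ii): keep
#' only designs whose above/below-median yield-event Brier skill score is
#' positive; if none survive, fall back to the static optimal design (the
#' fallback is flagged on the result). Step (iii): per year, choose the
#' surviving design with the highest ensemble-mean profit under that year's
#' member yields. Step (iv): realize the chosen design's profit under
#' observed (trace-0) weather.
#'
#' @inheritParams farmer_profile
#' @param skill_table optional precomputed [yield_event_skill()] table for
#'   these records (computed internally when `NULL`).
#' @return a `strategy_profile` with strategy `"forecast_optimal"` and
#'   attributes `kept_designs` and `bss_fallback`.
#' @export
select_forecast_designs <- function(records, econ = econ_params(),
                                    skill_table = NULL) {
  pm <- .profit_matrices(records, econ)
  .assert(!is.null(pm$ens), "ensemble traces missing",
          "cropval_coverage_error")
  if (is.null(skill_table)) {
    skill_table <- yield_event_skill(records, events = "above_median")
  }
  st <- copy(as.data.table(skill_table))[event == "above_median"]
  st[, design_id := .design_id(st)]
  kept <- st[BSS > 0]$design_id
  fallback <- length(kept) == 0L
  if (fallback) {
    kept <- optimize_static(records, econ)$design_by_year[1L]
  }
  keep_idx <- which(rownames(pm$obs) %in% kept)
  sub_ens <- pm$ens[keep_idx, , drop = FALSE]
  pick <- apply(sub_ens, 2L, which.max)
  ids <- rownames(sub_ens)[pick]
  realized <- pm$obs[cbind(match(ids, rownames(pm$obs)),
                           seq_along(pm$years))]
  out <- .make_profile("forecast_optimal", ids, realized, pm$years, econ)
  attr(out, "kept_designs") <- rownames(pm$obs)[keep_idx]
  attr(out, "bss_fallback") <- fallback
  out
}

#' Value report for one site x soil
#'
#' The three value numbers and downside-risk deltas:
#' `Value_optS = mean(static optimal) - mean(farmer)`,
#' `Value_optSCF = mean(forecast optimal) - mean(static optimal)`,
#' `Value_PK = mean(perfect knowledge) - mean(farmer)`.
#'
#' @param farmer,static_optimal,forecast_optimal,pk the four
#'   `strategy_profile`s on the same year set (`forecast_optimal` may be
#'   `NULL` when no ensemble run exists).
#' @param site,soil labels carried into the report.
#' @return a `value_report` list.
#' @export
value_report <- function(farmer, static_optimal, forecast_optimal = NULL,
                         pk = NULL, site = "site", soil = "soil") {
  profs <- Filter(Negate(is.null),
                  list(farmer = farmer, static_optimal = static_optimal,
                       forecast_optimal = forecast_optimal, pk = pk))
  yrs <- lapply(profs, `[[`, "years")
  .assert(all(vapply(yrs, identical, logical(1), y = yrs[[1]])),
          "strategy profiles must share the same year set",
          "cropval_input_error")
  out <- list(
    site = site, soil = soil,
    farmer = farmer, static_optimal = static_optimal,
    forecast_optimal = forecast_optimal, perfect_knowledge = pk,
    value_optS = static_optimal$mean_profit - farmer$mean_profit,
    value_optSCF = if (!is.null(forecast_optimal))
      forecast_optimal$mean_profit - static_optimal$mean_profit
    else NA_real_,
    value_PK = if (!is.null(pk)) pk$mean_profit - farmer$mean_profit
    else NA_real_,
    dsr_farmer = farmer$dsr,
    dsr_optimized = static_optimal$dsr,
    dsr_delta_optS = static_optimal$dsr - farmer$dsr,
    dsr_delta_optSCF = if (!is.null(forecast_optimal))
      forecast_optimal$dsr - static_optimal$dsr else NA_real_
  )
  structure(out, class = "value_report")
}

#' @export
print.value_report <- function(x, ...) {
  cat("<value_report>", x$site, "/", x$soil, "\n")
  cat(sprintf("  farmer %.0f | static %.0f | forecast %s | PK %s AU$/ha\n",
              x$farmer$mean_profit, x$static_optimal$mean_profit,
              if (is.null(x$forecast_optimal)) "-" else
                sprintf("%.0f", x$forecast_optimal$mean_profit),
              if (is.null(x$perfect_knowledge)) "-" else
                sprintf("%.0f", x$perfect_knowledge$mean_profit)))
  cat(sprintf("  Value_optS %.1f, Value_optSCF %s, Value_PK %s\n",
              x$value_optS,
              ifelse(is.na(x$value_optSCF), "-",
                     sprintf("%.1f", x$value_optSCF)),
              ifelse(is.na(x$value_PK), "-", sprintf("%.1f", x$value_PK))))
  invisible(x)
}

#' Flatten value reports to the exportable table
#' @param reports list of `value_report`s.
#' @return data.table matching the export contract (`site, soil,
#'   profit_farmer, profit_optimized, value_optS, value_optSCF, value_PK,
#'   dsr_farmer, dsr_optimized, dsr_delta`).
#' @export
value_report_table <- function(reports) {
  if (inherits(reports, "value_report")) reports <- list(reports)
  rbindlist(lapply(reports, function(x) data.table(
    site = x$site, soil = x$soil,
    profit_farmer = x$farmer$mean_profit,
    profit_optimized = x$static_optimal$mean_profit,
    value_optS = x$value_optS, value_optSCF = x$value_optSCF,
    value_PK = x$value_PK,
    dsr_farmer = x$dsr_farmer, dsr_optimized = x$dsr_optimized,
    dsr_delta = x$dsr_delta_optS)))
}
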