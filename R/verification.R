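#' Define a probabilistic forecast event
#'
#' @param kind `"above_median"`, `"tercile_1"` or `"tercile_3"`.
#' @param median,t1_upper,t2_upper climatological reference boundaries (same
#'   units as the verified values).
#' @return an `event_definition` list with the matching climatological base
#'   rate (0.5 for the median event, 1/3 for terciles).
#' @export
event_definition <- function(kind = c("above_median", "tercile_1",
                                      "tercile_3"),
                             median = NULL, t1_upper = NULL,
                             t2_upper = NULL) {
  kind <- match.arg(kind)
  base_rate <- if (kind == "above_median") 0.5 else 1 / 3
  structure(list(kind = kind, median = median, t1_upper = t1_upper,
                 t2_upper = t2_upper, base_rate = base_rate),
            class = "event_definition")
}

#' Event definition from a climatology row or reference sample
#' @param reference a numeric reference sample (boundaries are its type-7
#'   median and tercile quantiles) or a one-window [compute_climatology()].
#' @param kind event kind.
#' @return an `event_definition`.
#' @export
event_from_reference <- function(reference, kind = "above_median") {
  if (inherits(reference, "climatology")) {
    .assert(nrow(reference) == 1L, "need a single-window climatology",
            "cropval_input_error")
    event_definition(kind, median = reference$median,
                     t1_upper = reference$t1_upper,
                     t2_upper = reference$t2_upper)
  } else {
    q <- cv_quantile(reference, c(1 / 3, 0.5, 2 / 3))
    event_definition(kind, median = q[2], t1_upper = q[1], t2_upper = q[3])
  }
}

# event indicator with the package-wide tie rule: boundary values fall in
# the lower category
.event_indicator <- function(values, event) {
  switch(event$kind,
         above_median = as.integer(values > event$median),
         tercile_1 = as.integer(values <= event$t1_upper),
         tercile_3 = as.integer(values > event$t2_upper))
}

#' Binary event outcomes of observed window values
#'
#' Outcome 1 iff the value strictly exceeds the median (`above_median`) or
#' lies in the defined tercile; values exactly at a boundary fall to the
#' lower category.
#' @param values observed per-year values.
#' @param event an [event_definition()].
#' @return integer 0/1 vector.
#' @export
event_outcomes <- function(values, event) {
  .assert(length(values) >= 1, "empty value series", "cropval_input_error")
  .event_indicator(values, event)
}

#' Forecast probability of an event from a member distribution
#'
#' Fraction of distribution members satisfying the event, under the same
#' boundary tie rule as [event_outcomes()].
#' @param members forecast distribution (ensemble totals, analogue totals,
#'   member yields, ...).
#' @param event an [event_definition()].
#' @return probability in `[0, 1]`.
#' @export
forecast_probability <- function(members, event) {
  .assert(length(members) >= 2, "need >= 2 distribution members",
          "cropval_input_error")
  mean(.event_indicator(members, event))
}

#' Brier score, reference score and Brier skill score
#'
#' `BS = mean((p - o)^2)`, `BS_ref = mean((base_rate - o)^2)`,
#' `BSS = 1 - BS / BS_ref`: the proportional improvement of the issued
#' probabilities over the climatological reference forecast.
#'
#' @param probs issued probabilities in `[0, 1]`.
#' @param outcomes binary outcomes.
#' @param base_rate climatological base rate of the event.
#' @return list `(BS, BS_ref, BSS, n)`.
#' @export
brier_skill_score <- function(probs, outcomes, base_rate) {
  .assert(length(probs) == length(outcomes) && length(probs) >= 1,
          "probs and outcomes must be equal-length, non-empty",
          "cropval_input_error")
  .assert(all(probs >= 0 & probs <= 1), "probs must be in [0, 1]",
          "cropval_input_error")
  .assert(all(outcomes %in% c(0, 1)), "outcomes must be binary",
          "cropval_input_error")
  bs <- mean((probs - outcomes)^2)
  bs_ref <- mean((base_rate - outcomes)^2)
  .assert(bs_ref > 0, "reference Brier score is zero: skill undefined",
          "cropval_undefined_skill")
  list(BS = bs, BS_ref = bs_ref, BSS = 1 - bs / bs_ref,
       n = length(probs))
}

#' Percent consistent
#'
#' A forecast favours the event iff its probability exceeds the base rate
#' and the complement iff it falls below; forecasts exactly at the base rate
#' are excluded from the denominator. The result is
#' `100 * consistent / considered`.
#'
#' @inheritParams brier_skill_score
#' @return percentage in `[0, 100]` with attributes `n_considered` and
#'   `n_excluded`; `NA` (with a warning) when every forecast sits at the
#'   base rate.
#' @export
percent_consistent <- function(probs, outcomes, base_rate) {
  .assert(length(probs) == length(outcomes) && length(probs) >= 1,
          "probs and outcomes must be equal-length, non-empty",
          "cropval_input_error")
  considered <- probs != base_rate
  n_cons <- sum(considered)
  if (n_cons == 0L) {
    warning("all forecasts at the base rate: percent consistent undefined")
    return(structure(NA_real_, n_considered = 0L,
                     n_excluded = length(probs)))
  }
  favoured_event <- probs > base_rate
  consistent <- (favoured_event & outcomes == 1) |
    (!favoured_event & outcomes == 0)
  structure(100 * sum(consistent[considered]) / n_cons,
            n_considered = n_cons, n_excluded = length(probs) - n_cons)
}

#' Running-window skill
#'
#' A metric evaluated on every contiguous window of `window_years` issues,
#' indexed by the window's final year.
#' @inheritParams brier_skill_score
#' @param years issue years (same length as `probs`).
#' @param window_years window length (default 30).
#' @param metric `"bss"` or `"percent_consistent"`.
#' @return data.table `end_year, value`.
#' @export
running_skill <- function(probs, outcomes, years, window_years = 30L,
                          metric = c("bss", "percent_consistent"),
                          base_rate = 0.5) {
  metric <- match.arg(metric)
  o <- order(years)
  probs <- probs[o]; outcomes <- outcomes[o]; years <- years[o]
  uy <- unique(years)
  .assert(length(uy) >= window_years, "span shorter than the window",
          "cropval_input_error")
  ends <- uy[seq(window_years, length(uy))]
  vals <- vapply(ends, function(e) {
    keep <- years > e - window_years & years <= e
    if (metric == "bss") {
      brier_skill_score(probs[keep], outcomes[keep], base_rate)$BSS
    } else {
      as.numeric(percent_consistent(probs[keep], outcomes[keep], base_rate))
    }
  }, numeric(1))
  data.table(end_year = ends, value = vals)
}

#' Reliability diagram summary
#'
#' Issued probabilities are pooled into `n_bins` equal-width bins on
#' `[0, 1]`; per non-empty bin the mean issued probability and the observed
#' event frequency are reported. The slope `b` comes from a least-squares
#' regression of observed frequency on mean issued probability weighted by
#' bin counts, and `rmse` is the count-weighted root mean square residual of
#' that regression. The sharpness histogram is the per-bin forecast count.
#'
#' @inheritParams brier_skill_score
#' @param n_bins number of probability bins (default 10).
#' @return a `reliability_summary`: list with `bins` (data.table
#'   `bin_center, mean_prob, obs_freq, count`), `slope_b`, `rmse`,
#'   `sharpness_histogram`, `n`.
#' @export
reliability_curve <- function(probs, outcomes, n_bins = 10L) {
  .assert(length(probs) == length(outcomes) && length(probs) >= n_bins,
          "need at least n_bins forecasts", "cropval_input_error")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(probs, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts_all <- tabulate(bin, nbins = n_bins)
  dt <- data.table(bin = bin, p = probs, o = outcomes)
  bins <- dt[, .(mean_prob = mean(p), obs_freq = mean(o), count = .N),
             by = bin][order(bin)]
  bins[, bin_center := (edges[bin] + edges[bin + 1L]) / 2]
  setcolorder(bins, c("bin_center", "mean_prob", "obs_freq", "count"))
  bins[, bin := NULL]
  .assert(nrow(bins) >= 2L, "fewer than 2 non-empty bins: slope undefined",
          "cropval_undefined_slope")
  fit <- lm(obs_freq ~ mean_prob, data = bins, weights = bins$count)
  rmse <- sqrt(weighted.mean(residuals(fit)^2, bins$count))
  structure(list(bins = bins, slope_b = unname(coef(fit)[2]), rmse = rmse,
                 sharpness_histogram = counts_all, n = length(probs)),
            class = "reliability_summary")
}

#' @export
print.reliability_summary <- function(x, ...) {
  cat(sprintf("<reliability_summary> n = %d, slope b = %.3f, RMSE = %.3f\n",
              x$n, x$slope_b, x$rmse))
  print(x$bins)
  invisible(x)
}

#' Shift and dispersion of a forecast distribution against climatology
#'
#' `AMD = |mean(forecast) - mean(climatology)|` (shift, mm) and
#' `VR = var(forecast) / var(climatology)` (dispersion, sample variances).
#' @param forecast_totals forecast distribution members.
#' @param climatology_totals climatological reference sample.
#' @return list `(AMD, VR)`.
#' @export
shift_dispersion <- function(forecast_totals, climatology_totals) {
  .assert(length(forecast_totals) >= 2 && length(climatology_totals) >= 2,
          "both samples need >= 2 members", "cropval_input_error")
  vc <- var(climatology_totals)
  .assert(vc > 0, "zero climatological variance: VR undefined",
          "cropval_undefined_vr")
  list(AMD = abs(mean(forecast_totals) - mean(climatology_totals)),
       VR = var(forecast_totals) / vc)
}

#' Forecast skill of simulated yields for every design and event
#'
#' For each (environment, design) group the trace-0 (observed weather)
#' yields across years form the in-sample yield climatology; per year the
#' ensemble member yields give the issued event probability and the trace-0
#' yield the outcome. Brier skill score, percent consistent, reliability
#' slope/RMSE (when enough distinct probability bins exist) and mean
#' AMD/VR are reported per event kind.
#'
#' @param records a yield-record table from [simulate_factorial()] or the
#'   pipeline (columns `site, soil, isw, window, maturity, tillering,
#'   density, row_config, n_rate, year, trace, yield`).
#' @param events event kinds to verify.
#' @return data.table, one row per (group, event): the grouping columns
#'   plus `event, n, BS, BS_ref, BSS, percent_consistent, AMD, VR, slope_b,
#'   rmse`.
#' @export
yield_event_skill <- function(records,
                              events = c("above_median", "tercile_1",
                                         "tercile_3")) {
  rec <- as.data.table(records)
  keys <- intersect(c("site", "soil", "isw", "window", "maturity",
                      "tillering", "density", "row_config", "n_rate"),
                    names(rec))
  .assert(any(rec$trace == 0L), "observed-weather trace (0) missing",
          "cropval_coverage_error")
  out <- list()
  groups <- split(rec, by = keys, drop = TRUE)
  for (g in groups) {
    obs <- g[trace == 0L][order(year)]
    ens <- g[trace != 0L]
    .assert(nrow(ens) > 0, "ensemble traces missing",
            "cropval_coverage_error")
    .assert(all(obs$year %in% unique(ens$year)),
            "ensemble yields missing for some years",
            "cropval_coverage_error")
    ens_by_year <- split(ens$yield, ens$year)
    for (kind in events) {
      ev <- event_from_reference(obs$yield, kind)
      o <- event_outcomes(obs$yield, ev)
      p <- vapply(as.character(obs$year), function(y)
        forecast_probability(ens_by_year[[y]], ev), numeric(1))
      bss <- tryCatch(brier_skill_score(p, o, ev$base_rate),
                      cropval_undefined_skill = function(e)
                        list(BS = NA_real_, BS_ref = NA_real_,
                             BSS = NA_real_))
      pc <- suppressWarnings(
        as.numeric(percent_consistent(p, o, ev$base_rate)))
      sdis <- vapply(as.character(obs$year), function(y) {
        s <- tryCatch(shift_dispersion(ens_by_year[[y]], obs$yield),
                      cropval_undefined_vr = function(e)
                        list(AMD = NA_real_, VR = NA_real_))
        c(s$AMD, s$VR)
      }, numeric(2))
      rel <- tryCatch(reliability_curve(p, o),
                      error = function(e) list(slope_b = NA_real_,
                                               rmse = NA_real_))
      row <- g[1L, keys, with = FALSE]
      row[, `:=`(event = kind, n = length(p),
                 BS = bss$BS, BS_ref = bss$BS_ref, BSS = bss$BSS,
                 percent_consistent = pc,
                 AMD = mean(sdis[1, ]), VR = mean(sdis[2, ]),
                 slope_b = rel$slope_b, rmse = rel$rmse)]
      out[[length(out) + 1L]] <- row
    }
  }
  rbindlist(out)
}
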