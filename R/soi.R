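#' Default five-phase centroids in the (previous, current) index plane
#'
#' Centroids for the five named phases of the index pair classification, on
#' the sd-10 index scale: consistently negative, consistently positive,
#' rapidly falling, rapidly rising, near zero.
#' @return a 5 x 2 matrix with rownames the phase labels.
#' @export
default_phase_centroids <- function() {
  m <- rbind(
    consistently_negative = c(-10, -10),
    consistently_positive = c(10, 10),
    rapidly_falling = c(8, -8),
    rapidly_rising = c(-8, 8),
    near_zero = c(0, 0)
  )
  colnames(m) <- c("prev", "curr")
  m
}

#' Phase labels in fixed order (also the deterministic tie-break order)
#' @export
phase_labels <- function() rownames(default_phase_centroids())

#' Classify a consecutive monthly index pair into one of five phases
#'
#' Nearest-centroid assignment by Euclidean distance in the
#' (previous, current) plane; ties break deterministically by the fixed
#' label order of [phase_labels()].
#'
#' @param index_prev,index_curr consecutive monthly index values (finite).
#' @param centroids 5 x 2 centroid matrix, default
#'   [default_phase_centroids()].
#' @return a character phase label (vectorized over the inputs).
#' @export
classify_phase <- function(index_prev, index_curr,
                           centroids = default_phase_centroids()) {
  .assert(all(is.finite(index_prev)) && all(is.finite(index_curr)),
          "index values must be finite", "cropval_classification_error")
  .assert(length(index_prev) == length(index_curr),
          "index vectors must have equal length",
          "cropval_classification_error")
  d2 <- outer(index_prev, centroids[, "prev"], "-")^2 +
    outer(index_curr, centroids[, "curr"], "-")^2
  rownames(centroids)[apply(d2, 1L, which.min)]
}

#' Phase classification table for an index series
#'
#' One row per (year, month) with a defined consecutive pair (the first
#' month of the series has no predecessor and is omitted).
#' @param enso an [generate_enso_index()] series.
#' @param centroids centroid matrix.
#' @return data.table `year, month, index_prev, index_curr, phase`.
#' @export
soi_phase_table <- function(enso, centroids = default_phase_centroids()) {
  x <- as.data.table(enso)[order(year, month)]
  n <- nrow(x)
  out <- data.table(year = x$year[-1L], month = x$month[-1L],
                    index_prev = x$index[-n], index_curr = x$index[-1L])
  out[, phase := classify_phase(index_prev, index_curr, centroids)]
  out[]
}

#' Cross-validated analogue-year forecast for one issue
#'
#' Implements the phase-analogue statistical forecast: all reference years
#' whose issue-month phase matches the target year's phase, excluding the
#' target year itself (leave-one-out), form the analogue set; their observed
#' 3-month window totals are the forecast distribution, and category
#' probabilities are the fractions of that distribution above/below the
#' climatological median and inside each climatological tercile (boundary
#' ties fall to the lower category).
#'
#' When fewer than two analogue years remain, the forecast falls back to the
#' climatological distribution (all reference years except the target year)
#' and is flagged with `fallback = TRUE`; with `fallback = FALSE` an
#' `cropval_insufficient_analogues` error is raised instead.
#'
#' @param obs daily weather series.
#' @param enso matching index series.
#' @param issue list or vector with `year` and `month` of the issue.
#' @param climatology optional [compute_climatology()] result containing the
#'   issue window; computed from `obs` when `NULL`.
#' @param reference_years analogue reference years (default: all years with
#'   a complete window in `obs`).
#' @param centroids phase centroids.
#' @param fallback fall back to climatology on an empty analogue set?
#' @param totals_by_year,phase_table optional precomputed
#'   [window_totals()] / [soi_phase_table()] (loop efficiency).
#' @return an `analogue_forecast` object: list with `analogue_years`,
#'   `distribution` (mm), `category_probs`
#'   (`p_above`, `p_below`, `p_t1`, `p_t2`, `p_t3`), `phase`, `fallback`.
#' @export
analogue_forecast <- function(obs, enso, issue, climatology = NULL,
                              reference_years = NULL,
                              centroids = default_phase_centroids(),
                              fallback = TRUE, totals_by_year = NULL,
                              phase_table = NULL) {
  yr <- as.integer(issue[["year"]]); mo <- as.integer(issue[["month"]])
  tot <- totals_by_year %||% window_totals(obs, mo)
  if (is.null(reference_years)) reference_years <- as.integer(names(tot))
  if (is.null(climatology)) {
    climatology <- compute_climatology(obs, windows = mo,
                                       reference_years = reference_years)
  }
  cl <- climatology[climatology$window == mo]
  .assert(nrow(cl) == 1L, "climatology does not contain the issue window",
          "cropval_coverage_error")

  ph <- phase_table %||% soi_phase_table(enso, centroids)
  ph_issue <- ph[year == yr & month == mo]
  .assert(nrow(ph_issue) == 1L, "index does not cover the issue month",
          "cropval_classification_error")
  target_phase <- ph_issue$phase

  cand <- ph[month == mo & phase == target_phase & year != yr &
               year %in% reference_years]$year
  cand <- cand[as.character(cand) %in% names(tot)]
  used_fallback <- FALSE
  if (length(cand) < 2L) {
    .assert(fallback,
            sprintf("fewer than 2 analogue years for %d-%02d", yr, mo),
            "cropval_insufficient_analogues")
    cand <- setdiff(intersect(reference_years, as.integer(names(tot))), yr)
    used_fallback <- TRUE
  }
  dist <- unname(tot[as.character(cand)])

  p_above <- mean(dist > cl$median)          # ties fall below
  p_t1 <- mean(dist <= cl$t1_upper)
  p_t3 <- mean(dist > cl$t2_upper)
  probs <- c(p_above = p_above, p_below = 1 - p_above,
             p_t1 = p_t1, p_t2 = 1 - p_t1 - p_t3, p_t3 = p_t3)

  structure(list(
    site_id = attr(obs, "site_id") %||% "site",
    issue = list(year = yr, month = mo),
    target_months = .window_months(mo),
    phase = target_phase,
    analogue_years = as.integer(sort(cand)),
    distribution = dist,
    category_probs = probs,
    climatology = cl,
    fallback = used_fallback
  ), class = "analogue_forecast")
}

#' @export
print.analogue_forecast <- function(x, ...) {
  cat("<analogue_forecast>", x$site_id,
      sprintf("%d-%02d", x$issue$year, x$issue$month),
      "phase:", x$phase,
      if (x$fallback) "(climatology fallback)" else "", "\n")
  cat("  ", length(x$analogue_years), "analogue years; P(above median) =",
      round(x$category_probs[["p_above"]], 3), "\n")
  invisible(x)
}

#' Analogue-system hindcast over all issues of given window months
#'
#' Convenience wrapper running [analogue_forecast()] for every available
#' start year of the requested window months, returning issued probabilities
#' and realized binary outcomes ready for verification.
#'
#' @inheritParams analogue_forecast
#' @param months window start months to issue for.
#' @return data.table with one row per issue: `year, month, phase,
#'   n_analogues, fallback, p_above, p_t1, p_t3, outcome_above, outcome_t1,
#'   outcome_t3`.
#' @export
analogue_hindcast <- function(obs, enso, months = 1:12,
                              reference_years = NULL,
                              centroids = default_phase_centroids()) {
  ph <- soi_phase_table(enso, centroids)
  rows <- list()
  for (mo in months) {
    tot <- window_totals(obs, mo)
    yrs <- as.integer(names(tot))
    yrs <- yrs[yrs %in% ph[month == mo]$year]
    cl <- compute_climatology(obs, windows = mo,
                              reference_years = reference_years %||% yrs)
    for (yr in yrs) {
      fc <- analogue_forecast(obs, enso, list(year = yr, month = mo),
                              climatology = cl,
                              reference_years = reference_years %||% yrs,
                              centroids = centroids,
                              totals_by_year = tot, phase_table = ph)
      o <- tot[[as.character(yr)]]
      rows[[length(rows) + 1L]] <- data.table(
        year = yr, month = mo, phase = fc$phase,
        n_analogues = length(fc$analogue_years),
        fallback = fc$fallback,
        p_above = fc$category_probs[["p_above"]],
        p_t1 = fc$category_probs[["p_t1"]],
        p_t3 = fc$category_probs[["p_t3"]],
        outcome_above = as.integer(o > cl$median),
        outcome_t1 = as.integer(o <= cl$t1_upper),
        outcome_t3 = as.integer(o > cl$t2_upper)
      )
    }
  }
  rbindlist(rows)
}
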