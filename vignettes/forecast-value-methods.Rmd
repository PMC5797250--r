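---
title: "Methods: quantifying the value of seasonal forecast skill for crop design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the value of seasonal forecast skill for crop design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cropval)
```

`cropval` answers a decision-analytic question from dryland cropping: *how
much is skill in a probabilistic seasonal rainfall forecast worth when it is
used to choose a sorghum crop design?* A crop design (G×M) is one
combination of genotype traits (maturity class, tillering habit) and
management (plant density, row configuration, nitrogen rate); the
environment (E) is the site, soil water-holding capacity, initial soil
water at sowing, and sowing window. The package builds the entire chain at
desk scale: synthetic weather with a tunable ENSO-like teleconnection,
ensemble hindcasts with a tunable skill parameter, a five-phase analogue
statistical forecast, a transparent crop proxy, probabilistic verification,
and the economics of static versus forecast-informed design choice.

This vignette records the models, their assumptions, the parameters that
matter, and the design decisions that were genuinely open.

## Synthetic climate

**Daily weather.** Rain occurrence follows a first-order two-state Markov
chain with stationary monthly wet-day probabilities and a lag-1
persistence (default 0.25). Wet-day amounts are gamma distributed; monthly
gamma scales are derived from the target monthly means, which in turn come
from the annual mean (default 670 mm, a northern-grains-belt station value)
split by a fixed within-half-year shape scaled by `summer_fraction`
(default 0.64, the share of rain falling September–February). Maximum
temperature and radiation are annual harmonics plus Gaussian noise; the
diurnal range is truncated below 2 °C so `maxt >= mint` holds by
construction, and radiation is truncated at 1 MJ m⁻². Wet days are slightly
cooler and dimmer. Every generated series is a pure function of
`(params, seed)`.

**ENSO-like index.** A stationary AR(1) monthly series (default
persistence 0.8), standardized over the generated period to mean 0 and
standard deviation 10, the conventional pressure-index scale.

**Teleconnection.** The index modulates the monthly gamma scale
multiplicatively, `scale * (1 + beta * z)` with `z` the index on unit
scale. `beta` is solved in closed form from the generator's own variance
accounting so that the model correlation between September–February
rainfall totals and the mean September–February index equals the
configured `teleconnection_strength`: the weather-noise variance of the
seasonal total is assembled from the gamma amount moments and the
occurrence chain (including the `(1+r)/(1-r)` inflation from occurrence
persistence), the signal variance from the AR(1) autocovariances. A
Monte-Carlo test at 500 years recovers the target within ±0.1; a target too
close to the theoretical maximum (where weather noise would have to
vanish) raises a parameter error rather than silently clamping.

**Ensemble hindcasts.** Issues are the first of a month at lead 0; the
target is the three-month window starting with the issue month. On a
variance-stabilized (square-root) scale of window totals, with `a` the
standardized anomaly of the realized total and `rho` the skill parameter,
the generator draws a latent forecast signal and then members:

    s | a   ~  N(rho * a, 1 - rho^2)
    x_i | s ~  N(rho * s, 1 - rho^2)

The members are therefore samples from the true conditional climate given
the signal, which makes the system *calibrated by construction*: issued
event probabilities are reliable (slope ≈ 1), `cor(ensemble mean,
observation)` tends to `rho`, at `rho = 0` members reproduce climatology
(variance ratio → 1, mean shift → 0), and at `rho = 1` the conditional
distribution is degenerate at the observation. The obvious simpler
mechanism — centring members directly on the realized anomaly,
`x_i ~ N(rho * a, 1 - rho^2)` — is *not* calibrated (the outcome is then a
deterministic function of the issued probability, so the reliability curve
is a step function and the forecast–observation correlation is 1 for any
positive `rho`); we use the two-stage construction for exactly this
reason. Because event thresholds are quantiles, the square-root transform
and the clamp of negative stabilized values to zero leave median/tercile
event probabilities unchanged.

One finite-sample caveat: probabilities *estimated from a finite ensemble*
carry sampling noise (sd up to ≈ 0.05 at 99 members), and noise in the
regressor attenuates the reliability regression slope — a 99-member
ensemble whose underlying probabilities are perfectly calibrated shows an
expected slope of about 0.95, not 1.00, over a few thousand issues. This
is a property of reliability diagrams of finite ensembles generally, not
of this generator; with exact conditional probabilities the slope is 1
within sampling error.

Member daily traces are fresh synthetic window traces rescaled so their
rain totals equal the member totals (temperatures and radiation come from
the fresh trace). At `rho = 1` the member trace *is* the observed window
trace: the degenerate conditional distribution includes the daily pattern,
which is what makes the perfect-skill limit exact all the way through the
crop model and the decision layer.

**What the generator does not emulate.** Spatial coherence across sites,
skill in temperature or radiation (only rainfall skill is modulated),
regime changes and trends, and the within-season timing information a
dynamical model would carry. Passing tests therefore demonstrate the
machinery under stationary, calibrated, rainfall-only skill — not
performance on any real hindcast archive.

## The five-phase analogue system

Consecutive monthly index pairs are classified to the nearest of five
centroids in the (previous, current) plane — consistently negative
(−10,−10), consistently positive (+10,+10), rapidly falling (+8,−8),
rapidly rising (−8,+8), near zero (0,0) — with ties broken by the fixed
label order. The original phase clustering is not published in a
reproducible form; these centroids reproduce the five named behaviours and
are fully configurable.

An issue's forecast distribution is the observed window totals of all
reference years sharing the issue-month phase, *excluding the issue year
itself* (leave-one-out cross-validation, asserted over every issue in the
test suite). Category probabilities are fractions of that distribution
relative to the climatological median and terciles. An analogue set
smaller than two falls back to the climatological distribution and is
flagged and counted, which keeps long verification runs total.

## Crop proxy

The proxy is a daily water bucket, deliberately transparent rather than
faithful:

* **Phenology**: thermal time above a base of 11 °C; maturity at 1500 /
  1700 / 1900 °Cd for early / medium / late hybrids; canopy closes at 40 %
  of the maturity target.
* **Water**: `SW <- clamp(SW + rain - runoff - evap - transpiration, 0,
  PAWC)`. Intense rain (> 30 mm day⁻¹) sheds a fraction to surface runoff;
  bucket overflow counts as runoff/drainage so that the water balance
  closes to 10⁻⁶ mm (a tested invariant). Soil evaporation scales with
  bucket fullness and is shaded by canopy. Transpiration is the minimum of
  demand (7 mm day⁻¹ at full canopy and reference density, scaled by
  `(density/5)^0.35`, tillering multipliers 0.85/1.0/1.15, and 0.8 for
  single-skip rows) and supply (8 % of stored water per day).
* **Yield**: biomass = 0.018 t ha⁻¹ per mm transpired, capped by a
  Michaelis-type nitrogen ceiling `18 * N / (N + 60)` t ha⁻¹; yield =
  0.45 × capped biomass, bounded by a 12 t ha⁻¹ potential. Yields below
  0.2 t ha⁻¹ flag a failed crop (the published economics distinguish
  failed from harvested costs but not the criterion; 0.2 t ha⁻¹ makes the
  distinction operational).

The transpiration efficiency was set so that, at the farmer nitrogen rate,
the nitrogen ceiling binds in roughly the wettest third of seasons: yields
then respond to rainfall in most years while nitrogen investment still
pays in good seasons — the tension that gives a seasonal forecast economic
leverage. Monotonicity invariants (yield non-decreasing in PAWC, initial
soil water and in-crop rain; nitrogen response non-decreasing and
saturating) are enforced by property tests over seeded sweeps. Initial
soil water expressed volumetrically is mapped to a fraction of PAWC at
sowing — the simplest reading consistent with "more than 100 mm stored" at
60 % on a deep soil. Published PAW/PAWC pairs for the twelve study soils
are exposed verbatim as presets (including their internal inconsistency,
e.g. a PAW larger than PAWC at one site); only PAWC is used.

Yields do not target published station magnitudes — that is an explicit
non-goal; the proxy's job is to propagate rainfall signal and G×E×M
structure with auditable behaviour, not to reproduce the physiology of a
full cropping-systems model.

## Member seasons and the perfect-skill limit

A crop sown at the issue date outgrows the three-month forecast window
(≈ 110–160 days to maturity). Member seasons therefore splice the member
window trace onto *fresh climatological* weather for the remainder — not
the realized tail, which would hand a zero-skill ensemble genuine
information about the season (we measured mean yield-event Brier skill of
about +0.13 under that leak; with climatological tails the zero-skill
null is clean at ≈ 0). At `rho = 1` the conditional distribution of the
future is degenerate at the observation, so the whole member season is the
observed one; combined with the shared tie-break ordering this makes
forecast-informed choice and perfect knowledge *identical*, profit by
profit, at perfect skill — an exact, tested identity.

## Verification

Standard probabilistic scores for three event kinds (above/below median,
tercile 1, tercile 3; base rates 0.5 and 1/3):

* Brier skill score `BSS = 1 - BS / BS_ref` against the climatological
  base-rate forecast; exact limits (0 for the reference, 1 for a perfect
  forecast) are asserted, and the implementation is cross-checked against
  a naive per-item loop.
* Percent consistent: a forecast favours the event iff its probability
  exceeds the base rate; forecasts exactly at the base rate are excluded
  from the denominator (the published definition is verbal; this rule is
  symmetric and makes the denominator explicit). An all-at-base-rate
  series returns `NA` with a warning, never a silent zero.
* Reliability: ten equal-width probability bins; slope and RMSE from a
  least-squares fit of observed frequency on mean issued probability
  *weighted by bin counts*, which stabilizes sparse extreme bins; the
  sharpness histogram conserves the forecast count.
* Shift and dispersion: absolute mean deviation of the forecast mean from
  climatology, and the ratio of sample variances.
* Running skill: any metric on a sliding window of issues (default 30
  years), cross-checked against direct per-window calls.

Quantiles are type-7 (linear interpolation) throughout, and values exactly
on a boundary always fall in the lower category; both rules are fixed so
event outcomes are reproducible. Yield events use the in-sample trace-0
climatology across hindcast years (not cross-validated), mirroring how the
rainfall median is used; the choice is visible in the output metadata.

## Economics and the four-step search

Profit per hectare is `yield * price` net of insurance (1 % of gross), a
fixed variable cost (161 AU$ ha⁻¹ failed, 211 AU$ ha⁻¹ harvested), and
urea for nitrogen above a 50 kg N ha⁻¹ base (0.30 AU$ kg⁻¹ urea, 46 % N).
The published cost constants cannot all be literal simultaneously (the
161/211 totals, the 1 % insurance, and the per-kilogram urea cost
interact); the decomposition chosen here treats 161/211 as the
non-nitrogen, non-insurance costs, reproduces the failed-crop profit of
−161 exactly, and keeps nitrogen levels economically distinct. Downside
risk is the percentage of years with profit strictly below 600 AU$ ha⁻¹.

Four strategies are priced per site × soil in a fixed decision
environment (October sowing, 60 % initial soil water — the described
farmer practice, applied to all sites since only one site's practice is
printed):

1. **farmer** — the static described practice;
2. **static optimal** — the single design maximizing mean observed-weather
   profit (ties broken by lower nitrogen, lower density, then listed
   factor order; equals exhaustive search, tested against a brute-force
   oracle);
3. **forecast optimal** — the four-step search: build the design × year
   profit matrices; keep designs with positive above/below-median
   yield-event BSS (falling back, flagged, to the static optimum if none
   survive); per year pick the surviving design with the highest
   ensemble-mean profit (the simplest risk-neutral reading of "highest
   profit" — not median, not utility-weighted); realize the choice under
   observed weather;
4. **perfect knowledge** — the per-year hindsight optimum.

`Value_optS`, `Value_optSCF` and `Value_PK` are the mean-profit
differences (static−farmer, forecast−static, perfect−farmer); the three
identities, `Value_PK ≥ Value_optS`, and the pointwise dominance of
perfect knowledge are exact tested invariants. The published "Optimized"
column is read as the static optimum (its arithmetic, Optimized − Farmers,
matches the printed static value), and the two profiles are always
reported separately. No switching cost is applied to the forecast
strategy; none is published.

## Problem sizes and numerical choices

The reduced experiment used by the test suite and the acceptance script is
one site, three soils (PAWC 400/344/274 mm), five sowing windows, two
levels each of initial soil water, density, nitrogen, maturity, tillering
and row configuration, 35 hindcast years and 33 ensemble members —
1,142,400 crop-year simulations, enumerated and verified by the counting
operation. The daily bucket runs in compiled code; a full reduced run
takes well under a minute on one core. Monte-Carlo checks use 500-year
records (teleconnection, summer fraction, 2000-issue reliability) and a
300-year single-window run for the no-skill nulls. All randomness flows
through R's RNG under seeds derived from one master seed; identical
configuration and seed reproduce byte-identical CSV artifacts.

Known numerical edges: a member trace whose fresh synthetic window is
completely dry but whose total is positive receives its rain on six random
days; seasons are capped at 220 days and truncated at the cap if thermal
maturity is not reached (the generated sites are warm enough that this
does not occur); weather series are padded one calendar year past the
hindcast so January sowings complete.

## Limitations

The value numbers produced by the reduced experiment quantify the
machinery under the generator's assumptions; they are not estimates for
any real station, because the crop proxy is a deliberately simple water
bucket, the synthetic ensemble is not a dynamical hindcast, and the
decision environment fixes one
sowing window and soil-water state. Analysis-of-variance and
regression-tree partitioning of the verification table, gridded
verification, and plot rendering are out of scope by design — the tidy CSV
exports are the interface to those downstream analyses.
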