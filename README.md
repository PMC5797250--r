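# cropval

Quantifying the economic value of skill in probabilistic seasonal climate
forecasts for dryland sorghum **crop design** — the choice of a genotype ×
management combination (maturity, tillering habit, plant density, row
configuration, nitrogen rate) for an expected growing environment (site,
soil water capacity, initial soil water, sowing window).

Dryland sorghum profits hinge on in-crop rainfall that is unknown at
sowing. A skilful probabilistic forecast should let a grower swap the
design that suits an *average* season for one tuned to the *expected*
season. `cropval` builds the whole chain needed to price that swap at desk
scale, for climate-application researchers and agronomists who want a
transparent, fully seeded testbed:

* a stochastic daily weather generator (Markov-chain occurrence, gamma
  amounts, harmonic temperature/radiation) teleconnected to a persistent
  standardized ENSO-like index with a calibrated target correlation;
* 99-member ensemble hindcasts issued on the first of each month at lead 0
  for the coming 3-month window, with a skill parameter `rho` spanning
  no-skill (climatology) to perfect knowledge, calibrated by construction;
* the five-phase analogue statistical system (phase classification of
  consecutive monthly index values, leave-one-out analogue-year forecast
  distributions);
* a daily water-bucket sorghum proxy responsive to every factorial axis,
  with compiled inner loop and tested water-balance/monotonicity
  invariants;
* probabilistic verification: Brier skill score, percent consistent,
  reliability diagrams (slope *b*, RMSE, sharpness), running-window skill,
  and shift/dispersion (AMD, VR);
* a decision layer implementing the four-step, skill-filtered design
  search and the value equations.

## The statistics at the core

For issued probabilities `p_i` of an event with climatological base rate
`q` (0.5 for above/below median, 1/3 for terciles) and binary outcomes
`o_i`:

    BS    = mean((p_i - o_i)^2)
    BSref = mean((q - o_i)^2)
    BSS   = 1 - BS / BSref

Strategy value is measured against mean annual profit (AU$ ha⁻¹) of four
design strategies — farmer practice (GxM_f), the best static design
(GxM_optS), the yearly forecast-informed design (GxM_optSCF), and the
hindsight optimum (perfect knowledge):

    Value_optS   = Profit_GxM_optS   - Profit_GxM_f
    Value_optSCF = Profit_GxM_optSCF - Profit_GxM_optS
    Value_PK     = Profit_PK         - Profit_GxM_f

together with downside risk, the percentage of years with profit below
600 AU$ ha⁻¹. Profit uses a 254 AU$ t⁻¹ grain price, 1 % insurance on
gross, 161 / 211 AU$ ha⁻¹ variable costs for failed / harvested crops, and
urea at 0.30 AU$ kg⁻¹ for nitrogen above the 50 kg N ha⁻¹ base.

## Worked example

```r
library(cropval)

# a hand-checkable Brier skill score: two forecasts, both on the right side
brier_skill_score(c(0.8, 0.2), c(1, 0), base_rate = 0.5)
#> $BS      0.04
#> $BS_ref  0.25
#> $BSS     0.84

# the reduced experiment: 1 site, 3 soils, 5 sowing windows, 2 levels of
# each design factor, 35 hindcast years, 33 members  (~30 s, one core)
res <- run_reduced_experiment(reduced_experiment_config(skill_rho = 0.5,
                                                        seed = 1))
res$value_table
#>      site   soil profit_farmer profit_optimized value_optS value_optSCF value_PK
#> 1:  Dalby   high      644.4149         650.7006   6.285726            0 45.55181
#> 2:  Dalby medium      604.9576         612.7635   7.805928            0 30.45874
#> 3:  Dalby    low      543.9009         552.5684   8.667576            0 18.61539
#>    dsr_farmer dsr_optimized dsr_delta
#>      31.42857      28.57143 -2.857143
#>      37.14286      37.14286  0.000000
#>      62.85714      60.00000 -2.857143

res$value_reports[["Dalby_high"]]
#> <value_report> Dalby / high
#>   farmer 644 | static 651 | forecast 651 | PK 690 AU$/ha
#>   Value_optS 6.3, Value_optSCF 0.0, Value_PK 45.6

mean(res$yield_skill$BSS)   # mean above-median yield-forecast skill
#> 0.067
```

Reading the numbers: on the deep soil, committing to the best *static*
design is worth ≈ 6 AU$ ha⁻¹ per year over farmer practice and trims
downside risk by ~3 points; at intermediate ensemble skill (`rho = 0.5`)
the year-by-year forecast adjustment adds nothing beyond the static
optimum under this generator, while perfect foreknowledge would be worth
≈ 46 AU$ ha⁻¹ — skill has to be high before dynamic design switching pays.
Re-running with `skill_rho = 1` makes the forecast strategy coincide with
perfect knowledge exactly, so `value_optSCF = value_PK - value_optS`.

A stage-wise CSV pipeline (`run_pipeline()`, stages `synth`, `forecast`,
`simulate`, `verify`, `value`, with a manifest, dependency validation and
byte-identical reruns) and a thin CLI (`inst/cli/cropval.R`) wrap the same
functions.

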