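Package: cropval
Title: Value of Seasonal Climate Forecast Skill for Crop Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the economic value of skill in probabilistic seasonal
    climate forecasts for designing dryland sorghum crops. Provides a seeded
    stochastic daily weather generator with an ENSO-like teleconnected index,
    calibrated tunable-skill ensemble hindcasts, a five-phase analogue
    (SOI-phase style) statistical forecasting system, a transparent
    water-bucket sorghum yield proxy run over genotype x environment x
    management factorials, probabilistic verification (Brier skill score,
    percent consistent, reliability diagrams, shift and dispersion), and a
    decision layer that prices static and forecast-informed crop designs
    against farmer practice and perfect knowledge (Value_optS, Value_optSCF,
    Value_PK, downside risk).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
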