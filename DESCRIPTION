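Package: acrymoe
Title: Acrylamide Occurrence Surveys and Margin-of-Exposure Dietary Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing occurrence surveys of acrylamide in baked
    products and for deterministic dietary risk assessment. Provides
    censoring-aware summary statistics for per-sample concentration data,
    screening against EU Regulation 2017/2158 benchmark levels, analytical
    method-performance computations (calibration curve, LOD/LOQ, recovery,
    repeatability), comparative statistics (one-way ANOVA with Tukey HSD and
    compact letter display, Spearman rank correlation, locally weighted
    smoothing), a best/worst-scenario daily-intake grid, and margin-of-exposure
    risk characterisation against neurotoxic and carcinogenic benchmark-dose
    endpoints. A seeded synthetic-data generator fabricates occurrence,
    recipe, consumption and body-weight tables with the statistical structure
    the analysis assumes, including a survey-calibrated fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
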