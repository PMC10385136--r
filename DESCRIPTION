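Package: fopnl
Title: Front-of-Pack Nutrition Label Uptake Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring voluntary front-of-pack nutrition labeling
    (FOPNL) uptake in packaged-food launch databases, built around the Thailand
    Healthier Choice Logo (THCL) scheme. Standardizes back-of-pack nutrition
    information panels to per-100 g/mL, imputes fiber and fruit/vegetable/nut/
    legume (FVNL) content from ingredient lists, scores product healthfulness
    with a table-driven Health Star Rating (HSR) nutrient-profiling engine,
    classifies logo eligibility with a config-driven per-category criteria
    registry, and computes uptake proportions, closed-form linear trends with
    projections, chi-square comparisons, and stratified reports. Includes a
    calibrated synthetic product-database generator with ground-truth
    annotations so every pipeline stage is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
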