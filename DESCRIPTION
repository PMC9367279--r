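Package: darkcut
Title: Climatic and Feedlot Risk Modelling of Dark Cutting in Grain-Fed Beef
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying dark-cutting (high ultimate pH) risk in
    feedlot cattle from on-site weather records and production data. Computes
    black globe temperature, the temperature-humidity index (THI), the
    heat-load index (HLI) and the accumulated heat load balance from 15-minute
    weather observations; summarises thermal exposure over the week before
    each animal leaves the feedlot; merges feedlot and carcass-grading records
    by animal identifier; fits the base production-factor logistic model and
    climatic mixed-effects logistic models and reports odds ratios with Wald
    intervals; and generates synthetic weather, herds and outcomes with known
    coefficients for end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
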