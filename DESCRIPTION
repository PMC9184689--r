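Package: bdscreen
Title: Decision-Analysis Modelling of the Economic Impact of Screening for
    Unrecognised Bipolar Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-year decision-analysis cohort model quantifying the direct
    costs of bipolar disorder misdiagnosed as major depressive disorder in
    primary care, and the impact of one-time screening at any operating point
    of a screening test. Implements the screening cascade (confusion counts,
    predictive values, psychiatric referral, one-time costs), annual diagnosis
    correction, health-plan attrition and discounting; cut-off sweeps and
    scenario comparison; one-way sensitivity analysis; decision curve analysis;
    and a binormal score-population simulator that emulates cutoff tables of
    sensitivities and specificities with bootstrap confidence intervals.
    Closed-form and seeded microsimulation oracles validate the deterministic
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
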