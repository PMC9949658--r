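Package: ssbcra
Title: Comparative Risk Assessment of the Health and Economic Burden of
    Sugar-Sweetened Beverage Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates deaths, disease events, disability-adjusted life
    years (DALYs), overweight/obesity cases and direct medical costs
    attributable to sugar-sweetened beverage (SSB) consumption in a
    population, under a counterfactual of zero consumption.  Implements a
    comparative risk assessment with two causal pathways: a direct
    dose-response effect of SSB intake on type-2 diabetes and
    cardiovascular disease, and an indirect pathway mediated by body-mass
    index (BMI) for the remaining conditions.  Population attributable
    fractions are propagated to stratified burden totals, with Monte
    Carlo uncertainty on consumption and relative risks.  Ships a
    packaged Argentina 2020 input fixture and a synthetic-data generator
    with closed-form ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
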