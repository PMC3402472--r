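Package: cvdcea
Title: Generalized Cost-Effectiveness Analysis of Cardiovascular Disease
    Primary Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Markov cohort modelling and generalized (WHO-CHOICE style)
    cost-effectiveness analysis of lifestyle, pharmaceutical and
    population-wide interventions for primary prevention of ischaemic
    heart disease and stroke. Includes a synthetic risk-factor survey and
    epidemiology generator, absolute five-year risk stratification with
    calibration to observed event rates, multiplicative intervention
    effect algebra, a four-state discrete-time Markov cohort model with
    DALY/QALY weighting and discounting, a back-calculated 'do nothing'
    counterfactual, greedy expansion-pathway optimization, and Monte
    Carlo probabilistic sensitivity analysis with cost-effectiveness
    acceptability frontiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
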