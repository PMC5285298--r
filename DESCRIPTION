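Package: qofmobility
Title: Contract Choice and GP Mobility Under Pay-for-Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a practice-level pay-for-performance scheme
    (the UK Quality and Outcomes Framework) shapes contractual choices, quality
    provision and mobility in the primary-care labour market. Implements the
    closed-form equilibrium of a two-practice contract-choice game (salaried
    versus partnership contracts, competition for efficient doctors) together
    with an independent numeric best-response oracle; a QOF revenue engine with
    threshold-ramped points, price-per-point revenue and the 2005-to-2006
    exogenous price-shock construction; a seeded generator of a census-style
    doctor-by-practice panel whose outcomes follow the structural model; and
    the matching estimation suite (pooled OLS, linear probability models,
    random-intercept multilevel models, year-stratified probit with stacked
    inverse Mills ratios, and first-difference models with an exogenous price
    shock).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    geosphere,
    jsonlite,
    sandwich
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
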