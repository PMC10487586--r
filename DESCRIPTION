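Package: pharmcea
Title: Cost-Effectiveness Analysis of Pharmacist Adherence Interventions in HIV Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state Markov cohort model of HIV disease progression
    (WHO stages A/B/C plus death) with two-month cycles, used to evaluate
    the cost-effectiveness of pharmacist-led adherence support against
    usual care from a healthcare-payer perspective. Provides incremental
    cost-effectiveness ratios, net monetary benefit at GDP-based
    willingness-to-pay thresholds, one-way deterministic sensitivity
    analysis with tornado ordering and threshold-crossing solves,
    probabilistic sensitivity analysis with moment-matched beta and gamma
    input distributions and cost-effectiveness acceptability curves,
    calibration of transition matrices to arm-level outcome targets, and a
    synthetic two-arm trial generator with transition-matrix estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
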