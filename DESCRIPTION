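Package: prostcea
Title: Cost-Utility Analysis of Definitive Treatment for Low-Risk Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A monthly-cycle five-state Markov cohort model comparing
    hypofractionated intensity-modulated radiotherapy (20 fractions) with
    robot-assisted radical prostatectomy for localized low-risk prostate
    cancer from the Japanese healthcare-payer perspective. Accumulates
    discounted costs (JPY) and quality-adjusted life-years, computes
    incremental cost-effectiveness ratios and incremental net monetary
    benefit, and provides one-way (tornado) and probabilistic sensitivity
    analysis with beta/gamma/log-normal parameter sampling,
    cost-effectiveness acceptability curves, a sexual-dysfunction
    disutility-weight sweep, a Gompertz-Makeham synthetic life-table
    generator, and an individual-level microsimulation oracle for
    validating the cohort engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
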