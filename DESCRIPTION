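Package: baricea
Title: Cost-Utility Modelling of Bariatric Surgery Versus Conventional
    Medical Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decision-analytic state-transition (Markov) cohort model for
    the cost-utility analysis of bariatric surgery (gastric bypass, sleeve
    gastrectomy, adjustable gastric banding) compared with conventional
    medical management in severely obese adults, from a health-care payer
    perspective. The model tracks type 2 diabetes onset and post-surgical
    remission, cardiovascular disease (angina, myocardial infarction,
    stroke with tunnel states, transient ischemic attack, heart failure,
    peripheral artery disease), surgical complications and conversion
    surgery, and background cause-deleted mortality, in monthly cycles.
    Includes a synthetic-data module (Gompertz-Makeham life table with an
    ischemic-heart-disease fraction, placeholder Framingham-style risk
    equations, cohort fixtures), discounted cost and QALY accrual with
    incremental cost-effectiveness ratios and dominance verdicts, one-way
    deterministic sensitivity analysis with tornado output, probabilistic
    sensitivity analysis with cost-effectiveness plane and acceptability
    curves, subgroup batches and delayed-surgery scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
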