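Package: baricea
Title: Cost-Effectiveness Modelling of Bariatric Surgery in Type 2 Diabetes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model for the cost-utility
    analysis of bariatric surgery versus conventional medical management in
    morbidly obese patients with type 2 diabetes. Classifies patient-level
    one-year outcomes into five diabetes states, accrues lifetime discounted
    costs, life-years and quality-adjusted life-years over an annual-cycle
    Markov chain, computes incremental cost-effectiveness and cost-utility
    ratios with willingness-to-pay verdicts, and provides one-way
    deterministic sensitivity analysis with tornado ordering, time-horizon
    threshold analysis, and a synthetic cohort generator so the whole
    pipeline runs reproducibly without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
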