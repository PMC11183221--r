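Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis of Talazoparib in
    gBRCA-Mutated Advanced Breast Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov cohort model comparing talazoparib with
    physician's-choice chemotherapy for germline BRCA1/2-mutated,
    HER2-negative advanced breast cancer from the Chinese and United States
    healthcare perspectives.  Derives per-cycle transition probabilities
    from trial endpoint medians (overall survival, progression-free
    survival, duration of response) via a DEALE-style exponential
    approximation, runs a four-state cohort trace with half-cycle
    correction and discounting, values each arm in costs (USD) and
    quality-adjusted life years, and reports incremental
    cost-effectiveness ratios, net monetary benefit and GDP-threshold
    decision rules.  Includes one-way deterministic sensitivity analysis
    (tornado), seeded probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, bundled China/US parameter
    scenarios, and a microsimulation module for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
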