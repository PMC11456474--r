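Package: ceavte
Title: Markov Cohort Cost-Effectiveness Model for Primary Thromboprophylaxis
    of Cancer-Associated Venous Thromboembolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model comparing direct oral
    anticoagulants, low-molecular-weight heparins and no prophylaxis for the
    primary prevention of cancer-associated venous thromboembolism from a
    Chinese payer perspective.  The package ships the full base-case
    parameter table as a validated fixture, builds a tunnel-state transition
    model with competing monthly event branches (thrombosis, bleeding,
    death), propagates the cohort with discounted cost and QALY accrual, and
    layers standard decision-analytic output on top: incremental
    cost-effectiveness ratios with dominance classification, net monetary
    benefit, scenario grids over horizon and drug-price variants, one-way
    deterministic sensitivity analysis with tornado ordering and threshold
    search, and a seeded probabilistic sensitivity analysis feeding
    cost-effectiveness acceptability curves.  A random-effects pooling stage
    (DerSimonian-Laird on the logit scale) regenerates no-prophylaxis event
    rates from trial-arm counts when users supply them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    metafor
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
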