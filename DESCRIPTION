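Package: frailtybias
Title: Simulating Depletion-of-Susceptibles Bias in Cox Hazard Ratio Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scenario-driven Monte Carlo machinery for studying how an
    unmeasured susceptibility (frailty) biases Cox proportional-hazards
    estimates of a randomized treatment effect. Provides built-in scenario
    registries (binary and continuous susceptibility grids, trial-mimicking
    designs with event-count stopping, non-adherence, and replication series
    based on published time-dependent effects), event-time generators under a
    constant-baseline proportional-hazards model, the permutational algorithm
    for time-dependent exposures, overall, year-specific and last-period Cox
    estimators, a quadratic-spline time-dependent-coefficient Cox model with
    a likelihood-ratio test of proportional hazards, and replicate-level
    performance summaries (bias, relative bias, depletion curves, rejection
    and sign rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    splines,
    stats,
    utils,
    jsonlite,
    yaml,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
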