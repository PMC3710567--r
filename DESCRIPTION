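Package: ltssfa
Title: Stochastic Frontier Cost-Efficiency Analysis of State Long-Term
    Support Services
Version: 0.1.0
Authors@R: person("LTSS", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-step cost-efficiency analysis for state-level long-term
    support services (LTSS) panels. Step one fits a panel stochastic cost
    frontier with truncated-normal, time-varying-decay inefficiency by
    maximum likelihood and predicts state-year efficiency scores. Step two
    regresses log scores on home and community based services (HCBS) and
    policy covariates with state fixed effects, cluster-robust inference,
    and a Hausman fixed-versus-random-effects test. Includes panel
    ingestion with sample-construction rules and CPI deflation, a seeded
    synthetic-panel generator with ground-truth parameters for recovery
    testing, and ranking/quartile-trend reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    numDeriv
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
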