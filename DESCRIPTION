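Package: safenim
Title: Bayesian Sequential Non-Inferiority Monitoring of Safety Events
Version: 0.1.0
Authors@R:
    person("safenim", "maintainers", email = "safenim@example.org",
           role = c("aut", "cre"))
Description: Tools to build and apply a Bayesian sequential non-inferiority
    decision rule for rare dichotomous safety events. The non-inferiority
    margin is a full distribution, a mixture of up to three beta densities
    fitted from expert elicitation, rather than a fixed number. Conjugate
    beta-binomial posteriors are combined with the margin distribution to
    give the posterior probability of an unacceptable excess in the
    experimental arm, compared at each interim analysis against a
    decreasing threshold schedule. Priors and thresholds are calibrated by
    simulation against severity-weighted misclassification constraints.
    Includes seeded generators for synthetic elicitation answers and trial
    datasets, CSV/JSON/YAML interfaces and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
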