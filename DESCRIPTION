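Package: emdisc
Title: Evolutionary Model Discovery for Agent-Based Decision Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers and ranks the causal factors behind an agent decision
    rule in a household-level demographic simulation. Provides an annual-step
    agent-based model of subsistence maize farmers with a pluggable
    farm-plot-selection strategy, a strongly-typed genetic program that evolves
    selection rules from hypothesized social, emotional and rational factors,
    and a random-forest importance pipeline (impurity, permutation and
    decision-path joint contributions) that ranks factors by their contribution
    to simulation fitness. Includes a synthetic-landscape generator with
    planted generating rules for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    ranger,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
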