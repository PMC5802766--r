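Package: matesim
Title: Agent-Based Simulation of Mating-System Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An individual-based model of the evolution of male mating
    strategies (monogamy with mate guarding versus polygamous mate
    searching) on a grid of fixed, regularly spaced female territories.
    Provides the seeded per-tick simulator, heritable-trait genetics with
    Gaussian threshold mutation, a parameter-sweep harness with the
    percentage-monogamy outcome, and normalized multiple-regression
    summaries of sweep results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
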