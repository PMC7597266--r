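Package: qga
Title: Quantitative Genetic Algorithm for Derivative-Free Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivative-free optimization by deterministic natural selection.
    A population of candidate solutions (phenotypes) carries Boltzmann
    selection weights whose scale is tuned each iteration so that population
    entropy stays at a target value; new candidates are generated by a
    covariance-preserving whole-population recombination operator, so no
    covariance matrix is ever stored or factorized inside the optimizer.
    Includes the supporting population-genetics theory layer: replicator
    dynamics and its natural-gradient form, closed-form Gaussian selection
    dynamics on quadratic fitness landscapes (including the Newton-step
    limit), diversity and genetic-load diagnostics, a Moran birth-death
    extinction simulator, built-in benchmark landscapes, and a small
    command-line and benchmarking harness.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
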