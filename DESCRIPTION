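Package: mosid
Title: Minimal Output Sets for Structural Identifiability of ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical structural-identifiability analysis for ordinary
    differential equation models via the singular value decomposition of the
    normalized output sensitivity matrix, and an iterative sensor-omission
    search that enumerates all minimal output sets: the smallest subsets of a
    model's predefined outputs whose measurement guarantees that unique
    parameter values (including unknown initial conditions) can be inferred.
    Includes a declarative plain-text model format, forward (variational)
    sensitivity integration, a rank test based on gaps in the singular
    spectrum, correlated-parameter diagnosis from near-null right singular
    vectors, minimal-hitting-set enumeration over omitted-sensor families,
    Bernoulli-sampled sweeps for large sensor pools, and a numeric
    first-order invariance check that confirms detected parameter
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
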