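Package: dynamet
Title: Automated Construction of Parameterised Dynamic Metabolic Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds parameterised kinetic (ODE) models of metabolic
    reaction networks from an SBML network description. Kinetic rates are
    gathered from registered database adapters by exhaustive identifier-path
    search with full provenance, combined by thermodynamically consistent
    Bayesian parameter balancing (Haldane relationships and Wegscheider
    cycle conditions), translated into common modular rate laws and
    simulated. Includes flux-variability-based model reduction (pruning and
    linear-pathway compression), a synthetic network and fixture-database
    generator, and a robustness-analysis harness that quantifies how the
    fraction and precision of known kinetic parameters determine the
    accuracy of simulated dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    deSolve,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
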