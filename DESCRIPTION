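Package: rootbox
Title: Stochastic 3D Root System Architecture Simulation and Order-Based
    Trait Analysis for Split-Root Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-dimensional root system architectures growing in a
    vertically partitioned (split-root) box, using a stochastic growth model
    parameterized per root branching number and per compartment: constant
    elongation capped at a maximum length, lateral insertion at a fixed
    branching interval outside basal and apical unbranched zones, normally
    distributed insertion angles, and a gravitropic tropism with heading noise.
    Computes order-based root traits (branching intensity, density and ratio,
    specific root length, mass fractions, allocation proportions) and relative
    elongation rates from root-trace time series, generates synthetic
    split-root experiments with resource-mixed and resource-partitioned
    treatments, and provides exact binomial proportion tests and one-way ANOVA
    for compartment comparisons. Root architectures are exchanged as RSML 1.0
    documents and growth parameters as TOML configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
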