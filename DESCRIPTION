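Package: thermaxon
Title: Temperature-Robust Action Potential Timing in Model Axons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation of action-potential propagation along
    unmyelinated Hodgkin-Huxley cable axons with per-property Q10 temperature
    scaling of channel conductances and gating kinetics. Enumerates exhaustive
    sweeps of channel-property Q10 combinations across axon diameters and
    temperatures, and derives the timing statistics of the resulting model
    database: conduction-velocity Q10s, inter-axon arrival-time delay matrices,
    temperature-robustness classification, delay-versus-Q10-ratio regressions,
    necessity/sufficiency tests of coordinated Sodium-channel temperature
    sensitivities, and coefficient-of-variation analyses. Includes a synthetic
    generator of per-animal velocity-versus-temperature recordings and a
    phase-constancy pipeline for central-pattern-generator timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
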