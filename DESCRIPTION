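Package: nanosorb
Title: Adsorption Isotherms, Kinetics and Aggregation Metrics for Drug-Loaded Carbon Nanotubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the batch-adsorption analysis of doxorubicin (DOX) on
    carbon nanotubes: mass-balance uptake capacities from spectrophotometric
    standard curves, equilibrium isotherm fitting (Freundlich, Langmuir,
    Temkin) in linearized and nonlinear modes, adsorption-kinetics fitting
    (pseudo-first order, pseudo-second order, two-segment Weber-Morris
    intra-particle diffusion, fractional power, Elovich) with model-selection
    diagnostics, an ideal zigzag single- and multi-wall nanotube coordinate
    generator, and configuration metrics for point-reduced molecular
    trajectories (single-linkage aggregate detection under periodic
    boundaries, surface-adsorbed fraction, ring-decomposition interior
    occupancy). Synthetic-data generators with exact ground truth support
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
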