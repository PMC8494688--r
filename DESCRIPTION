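Package: rhizofate
Title: Mechanistic Soil-Root Pesticide Uptake Modelling in 3D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coupled simulation of variably saturated soil water flow
    (Richards equation with van Genuchten-Mualem layered properties),
    root-network hydraulics on explicit 3D root architectures
    (Doussan-type xylem solve with collar switching between
    flux-controlled and water-potential-controlled transpiration),
    soil solute transport and fate (finite-volume advection, impeded
    diffusion, linear equilibrium sorption, first-order degradation
    modified by moisture, temperature and depth), and passive root
    solute uptake combining diffusive membrane permeability with
    partially excluded advective uptake. Root architectures can be read
    from RSML, generated as a single vertical axis, or grown with a
    seedable stochastic maize-like generator. Diagnostics include the
    transpiration stream concentration factor (TSCF), plant uptake
    factor (PUF), standard uptake fraction (SUF), per-layer cumulative
    water and solute sinks, and full water and solute mass ledgers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
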