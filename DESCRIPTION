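Package: gliosphere
Title: Continuum Simulation of Glioma Spheroid Growth in an Elastic
    Extracellular Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic one-dimensional (spherically symmetric) continuum
    simulator of avascular multicellular tumor spheroid growth in a porous
    elastic extracellular matrix.  The model couples three cell phenotypes
    (proliferative, hypoxic, necrotic) switching on local oxygen thresholds,
    oxygen diffusion and consumption, an adhesion-based intercellular stress
    law, quasi-static linear elasticity of the compressible matrix, and
    stress-gradient cell drift with optionally strain-dependent matrix
    permeability.  Numerical kernels include a conservative Crank-Nicolson
    spherical diffusion solver, flux-corrected transport (SHASTA-type)
    advection, and a second-order displacement boundary-value solver.
    Post-processing utilities extract density isolines, invasion speeds,
    proliferative-rim inventories and hypoxic fractions from simulated
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
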