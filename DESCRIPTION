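Package: idrsuite
Title: Coarse-Grained Phase-Separation Simulation and Solution-State Analysis of Disordered Protein Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing intrinsically disordered protein regions
    that undergo liquid-liquid phase separation. Provides a one-bead-per-residue
    coarse-grained Langevin simulator with Debye-Hueckel screened electrostatics
    and a hydropathy-scaled Ashbaugh-Hatch potential, a staged droplet-formation
    protocol (minimization, NVT, NPT with Berendsen pressure coupling, box-density
    reset, production), intermolecular contact-map and interaction-fraction
    analysis, small-angle X-ray scattering analysis (Guinier, dimensionless
    Kratky, pair-distance distribution, Debye chain fits, molecular-weight
    estimators), circular-dichroism spectrum arithmetic, sequence composition
    profiling, and seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    igraph,
    seqinr,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
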