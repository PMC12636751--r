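Package: neuritesim
Title: Coarse-Grained Bead-Spring Simulation of Neurite Protrusion Mechanics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional coarse-grained bead-spring model of a cell
    (plasma-membrane ring, nuclear-envelope ring, and radial actin filaments
    with tip beads) evolved by overdamped Langevin dynamics with stochastic
    filament growth. The membrane-actin adhesion depth U3 models cortical
    tension and the discrete bending stiffness kappa00 models membrane
    elasticity; sweeping the two maps when neurite-like membrane protrusions
    nucleate, extend, and persist. Includes outline morphometrics (projection
    length, protrusion count, circularity, stability), seeded replicate
    sweeps and phase diagrams, a lossless text trajectory format, extended-XYZ
    export, SVG/PNG snapshot rendering, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
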