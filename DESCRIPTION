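Package: ovulegrowth
Title: Mechanical Growth Simulation and Morphometrics of the Arabidopsis
    Ovule Primordium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-dimensional tissue growth simulators (a cell-based
    mass-spring engine with turgor and elasto-plastic walls, and a
    continuum finite-element engine with anisotropic material and
    eigenstrain growth) for the Arabidopsis ovule primordium, together
    with the morphometric and statistical pipeline used to analyse
    simulated or segmentation-derived data: organ outline height and
    width from curvature extrema, covariance-eigenvalue cell shape
    anisotropy, bounding-box occupancy, developmental stage
    classification, domain-resolved mitotic frequency maps, and
    spore-mother-cell canalization statistics based on exact Fisher
    tests.  A seeded synthetic-data module generates label stacks, cell
    descriptor tables and scoring tables with stored ground truth so the
    whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
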