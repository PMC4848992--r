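Package: anthraqsar
Title: 2D- and 3D-QSAR Modelling of Anthranilic Acid FXR Partial Agonists
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) workflow for
    a series of anthranilic acid derivatives acting as partial agonists of the
    farnesoid X receptor (FXR). Provides physicochemical descriptor
    calculation (rotatable bonds, relative negative partial charge, Oprea
    lead-likeness, SlogP_VSA2, solvent-accessible surface area), stepwise
    multiple linear regression with full internal and external validation
    (leave-one-out Q2, F statistics, Y-randomization), applicability-domain
    analysis via hat-matrix leverages and Williams plots, and a comparative
    molecular field analysis (CoMFA)-style 3D-QSAR engine: lattice
    construction over aligned conformers, Lennard-Jones steric and Coulomb
    electrostatic probe fields, column filtering, NIPALS partial least
    squares with leave-one-out component selection, field contributions and
    contour grids. Ships the 41-compound activity table of the modelled
    series as a packaged fixture together with seeded synthetic-data
    generators so every stage is testable offline. Structure handling (SMILES
    parsing, seeded 3D embedding, Gasteiger charges) is delegated to RDKit
    through a small packaged Python helper.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH
Config/testthat/edition: 3
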