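Package: fieldpharm
Title: Field-Based 3D-QSAR Pharmacophore Modelling and Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grid-field three-dimensional quantitative structure-activity
    relationship (3D-QSAR) pharmacophores for aligned small-molecule sets.
    Projects per-atom descriptors (atomic log P contributions, hydrogen-bond
    donor/acceptor indicators, partial charges, steric terms) onto a regular
    lattice with an exponential decay function, or computes CoMFA-style
    Coulomb and Lennard-Jones probe energies, then fits partial least-squares
    models with leave-one-out cross-validation. Includes external-validation
    regression diagnostics, ROC/AUC and early-enrichment metrics for
    active/decoy discrimination, rank-overlap comparison of models, urea
    substructure filtering, docking-pose selection and pharmacophore-based
    reranking of screening candidates, coefficient contour-map export, and a
    synthetic aligned-ligand generator with known field-to-activity ground
    truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
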