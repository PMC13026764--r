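Package: ensdyn
Title: Assessment of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative comparison of protein conformational ensembles:
    per-residue flexibility (RMSF) and its profile correlation, dynamic
    cross-correlation matrices (DCCM) and mean absolute error, distance-based
    residue contact maps, stratified breakdowns (terminal regions, sequence
    separation, interaction chemistry), distribution-shift quantification
    between wild-type and variant ensembles via PCA projection and
    Kullback-Leibler divergence on shared-bin 2D histograms, two-state
    (apo/holo) RMSD projection and occupancy summaries, pocket-exposure
    scoring with adaptive cutoff filtering and clustering-based selection of
    receptor structures for ensemble docking, and virtual-screening
    evaluation metrics (ROC AUC, enrichment at 1% FPR, top-N hits). Includes
    seeded synthetic-ensemble generators with known ground truth so every
    stage can be exercised without external trajectory data. Reads
    multi-model PDB, DCD and XTC trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
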