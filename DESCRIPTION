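Package: ciliabase
Title: Quantitative Analysis of the Multiciliated-Cell Ciliary Base
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry and interactome analysis tools for in situ structural
    studies of the ciliary base of multiciliated cells. Resamples traced
    filaments into oriented particle sets for subtomogram averaging, sharpens
    noisy per-particle class labels into ordered ciliary subzones by
    nearest-neighbour voting and ordering-constrained segmentation, measures
    barrel diameters and zone lengths, quantifies the ciliary-necklace
    membrane lattice (row count, in-row spacing, per-doublet stoichiometry)
    on unrolled cylindrical membranes, builds two-engine consensus
    cross-linking mass-spectrometry interactomes with Calpha distance
    restraint mapping onto atomic models, and computes expansion-microscopy
    expansion factors and transition-zone lengths. Ships ground-truthed
    synthetic data generators so every stage is testable without deposited
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
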