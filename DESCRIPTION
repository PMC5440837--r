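Package: groovedock
Title: Template-Guided Docking of Transmembrane Helix Bundles and
    Co-Localization Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a groove-bearing transmembrane (TM) helix
    bundle (such as the mitochondrially encoded complex I subunit ND2) docks
    onto the protruding M4 helix of an ionotropic receptor (such as the NMDA
    receptor GluN1 subunit). Implements template-guided rigid-body docking
    (Kabsch superposition of a homologue's groove-filling helix onto the target
    M4, followed by a clash-minimizing rotation scan about the M4 axis),
    Shrake-Rupley solvent-accessible surface area and buried interface area,
    contact maps and groove-lining helix identification. Also provides the
    quantitative assay statistics used alongside such models: Costes-thresholded
    Pearson co-localization coefficients for two-channel cell images,
    bimolecular fluorescence complementation (BiFC) scoring with fold-over-
    background classification, Kruskal-Wallis/Dunn and Welch ANOVA group tests,
    and Stretcher-style global protein alignment with identity and similarity
    percentages. A synthetic-data module generates idealized TM bundles,
    planted docking scenes, two-channel images with known co-localized
    fraction, and BiFC intensity tables, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
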