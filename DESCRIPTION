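Package: dropmapr
Title: Single-Cell Droplet Immunoassay Analysis of Antibody Secretion and Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for droplet-microfluidic single-cell secretion
    assays in which antibody secreted by a cell inside a water-in-oil droplet
    is captured on a magnetic nanoparticle beadline and quantified by
    fluorescence relocation in time-lapse two-channel microscopy. Provides a
    synthetic emulsion and image-stack generator with per-droplet ground
    truth, droplet and beadline segmentation, relocation trace extraction and
    quality control, threshold-based calling of IgG-secreting cells,
    calibration-based inversion of relocation kinetics into single-cell IgG
    secretion rates (molecules/s) and equilibrium dissociation constants for
    the antigen, serum-level computations (steady-state surface plasmon
    resonance affinity fit, anti-antigen IgG percentage, censored ELISA ED50),
    and censoring-aware cohort summaries with rank-based comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
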