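Package: tjscope
Title: Tight-Junction Barrier Function and Single-Molecule Localization
    Microscopy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for single-monolayer
    tight-junction studies on Transwell filters. Quantifies barrier
    function (blank-corrected, area-normalized transendothelial
    electrical resistance and FITC-dextran flux against a calibration
    curve), junction-associated immunofluorescence from widefield
    z-stacks (maximum-intensity projection, tile stitching, per-area
    intensity in annotated junction regions), and single-molecule
    localization microscopy (SMLM): per-frame spot detection, 2D
    Gaussian sub-pixel fitting with uncertainty estimates, pairwise
    distance clustering spectra against a complete-spatial-randomness
    reference, and coordinate-based two-channel colocalization. A
    synthetic-data generator produces junction geometries, blinking
    EMCCD movies, widefield images and functional records with known
    ground truth, so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
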