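Package: afmforce
Title: AFM Force-Spectroscopy Analysis of Cell Mechanics, Adhesion and
    Protein Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for atomic force microscopy (AFM)
    force-distance curves covering three measurement modes: cell
    indentation (Hertz theory with the Sneddon extension for four-sided
    pyramidal indenters, Young's modulus at fixed depth and indentation at
    fixed force), single-cell adhesion (detachment-point detection and
    work-of-adhesion integration of the retract curve), and single-molecule
    polyprotein unfolding (sawtooth peak detection, worm-like-chain fits at
    fixed persistence length, contour-length-increment classification and
    Bell-Evans rate dependence). Includes a synthetic force-curve generator
    with known ground truth for every mode, population statistics (lognormal
    fits with mode extraction, kernel density, percentile summaries) and
    exact Mann-Whitney two-group comparison, plus a documented plain-text
    curve container for reproducible round-tripping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
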