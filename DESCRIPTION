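Package: dpphplate
Title: Scanner-Based DPPH Radical-Scavenging Assay Quantification
Version: 0.1.0
Authors@R:
    person("Plate", "Densitometry Project", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spectrophotometer-free read-out of the DPPH (2,2-diphenyl-1-
    picrylhydrazyl) radical-scavenging assay from scanned plate images.
    Quantifies dropped reaction-mixture spots on TLC plates as mean grey
    values inside circular regions of interest, builds dose-response curves
    over serial-dilution ladders, and estimates half-maximal scavenging
    concentrations: SC50 from absorbance readings and CSC50 from colour
    values, by half-maximum interpolation and by the first-derivative
    (steepest-slope) method. Includes assay-validation statistics (LOD, LOQ,
    coefficient of variation, cross-method agreement) and a synthetic
    plate-image simulator that provides ground truth for testing the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    jpeg,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
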