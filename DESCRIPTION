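Package: cryosizer
Title: Automated Detection and Sizing of Extracellular Vesicles and
    Lipoproteins in Cryo-EM Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for automated characterization of
    sub-micrometre particles in defocused cryo-electron micrographs:
    supervised per-pixel segmentation of extracellular-vesicle lipid
    bilayers, lipoproteins (HDL/LDL/VLDL), exomere-like dense particles
    and surface-ice contamination; Hough circle transform detection of
    complete and partial bilayer rings; area-equivalent and ring-radius
    particle sizing with artifact exclusion (carbon-hole rims, ice);
    and size-distribution statistics. Includes a seeded synthetic
    micrograph simulator with per-particle ground truth so every stage
    is verifiable without microscope data, plus matching and
    precision/recall evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
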