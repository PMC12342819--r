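Package: iricrest
Title: Reconstruction of Iridescent Structural Color from Melanosome Nanostructure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the angle-dependent iridescent coloration produced by densely
    packed rod-like melanosomes in feather barbs, as measured from electron-microscopy
    cross-sections. Builds an asymmetric compact hexagonal packing (ACHP) lattice of
    elliptical melanosome cross-sections under a keratin cortex, solves Maxwell's
    equations for oblique-incidence reflectance with a from-scratch 2D
    finite-difference time-domain (FDTD) solver (Bloch-periodic lateral boundaries,
    CPML absorbers) and with an exact 1D transfer-matrix model of the reduced
    multilayer, extracts reflection peaks, renders CIE colorimetric swatches, and
    quantifies sensitivity of the predicted peaks to taphonomic shrinkage and spacing
    changes. Includes a synthetic electron-microscopy image generator and morphometry
    stage so the full measurement-to-color pipeline can be exercised and validated
    without fossil material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
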