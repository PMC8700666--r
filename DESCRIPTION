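Package: icemorph
Title: 3D Morphometry of Ice in Frozen Porous Food Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative 3D image analysis of micro-CT scans of frozen
    porous foods (e.g. sponge cake). Provides three-phase grey-level
    segmentation of air, ice and starch, construction of the closed starch
    matrix by 3D morphological closing, localization of ice inside versus
    outside the matrix, and morphometric descriptors: phase volume
    fractions, vertical fraction profiles, specific surface area (Crofton
    13-direction estimator), local thickness (exact Euclidean distance
    transform with sphere superposition), interface mean curvature from a
    smoothed indicator field, and representative-elementary-volume
    convergence analysis. Includes a synthetic phantom generator for frozen
    porous microstructures with exact ground-truth labels, closed-form
    thermophysical calculations (water content, freezable water from DSC
    enthalpy, mixture density, density-based porosity), and an end-to-end
    reporting pipeline. Results are returned as tibbles with ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
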