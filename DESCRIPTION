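Package: memcurve
Title: Membrane Curvature, Coat Occupancy and Symmetry Analysis for Cryo-ET Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis of segmented cryo-electron tomograms and
    cryo-EM density maps of membrane-remodeling protein assemblies. Reads and
    writes MRC volumes, cleans label volumes, extracts membrane surfaces with
    normals and principal curvatures, quantifies protein-coat occupancy as a
    function of membrane curvedness with a saturation (ramp-plateau) fit,
    prepares subtomogram-style particle sets (minimum spacing, normal-derived
    orientation priors, curvature clustering, orientation-consensus filtering),
    determines cyclic (Cn) symmetry of ring or patch densities by
    self-correlation maximization over symmetry order, axis offset and rotation,
    and measures radial/axial density profiles of membrane tubes (bilayer
    leaflet radii, thickness, outer diameter, constriction kink angle). A
    synthetic-scene generator produces vesicle/tube/ring phantoms with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
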