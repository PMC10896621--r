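Package: bovimorph
Title: Simulated Multi-View Depth Acquisition and 3D Morphometry of Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional phenotyping of dairy cattle from
    triangulated body meshes. Generates parametric, watertight cow-like
    meshes with analytically known traits; simulates a one-shot multi-camera
    depth-acquisition rig (depth rendering, quantization, edge-preserving
    smoothing, extrinsic calibration, point-cloud fusion and implicit
    surface reconstruction); extracts nine morphological traits plus partial
    and total volume and surface from a mesh and a landmark table; converts
    partial to total measures and predicts body weight with published linear
    equations; and computes ISO-style repeatability and reproducibility
    statistics (one-way ANOVA residual SD, coefficients of variation, 95%
    limits) and device-comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
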