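Package: limbmetric
Title: Validation Toolkit for Photogrammetric Residual-Limb Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry and statistics for validating smartphone-photogrammetry
    reconstructions of prosthetic residual limbs against CT-derived ground
    truth. Provides triangle-mesh primitives and I/O (PLY, STL, OBJ),
    sharpness-based video frame selection, metric scaling from square fiducial
    tag maps (two-stage Perspective-n-Point and joint tag/camera optimization),
    slab-wise CT outer-shell extraction (Otsu thresholding, cavity-removing
    binary propagation, signed distance fields, isosurface extraction),
    two-stage rigid registration (FPFH/RANSAC coarse, multi-scale point-to-plane
    ICP fine), the clinical accuracy metric suite (mean radial error, RMSE, IQR,
    Hausdorff distance, mean angular error, per-slice perimeter and ROI volume
    errors with threshold compliance), inter-session repeatability maps with
    minimal detectable change, and parametric limb phantoms for synthetic
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
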