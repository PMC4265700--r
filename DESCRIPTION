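Package: kneeseg
Title: Segmentation-Algorithm Benchmarking for 3D Bone Reconstruction from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares edge-detection segmentation algorithms (Sobel, Laplacian
    of Gaussian, Canny) for reconstructing 3D bone surface models from CT slice
    stacks. Provides slice-wise segmentation into closed contours, contour
    rasterization and shape-based slice interpolation, isosurface extraction to
    triangulated meshes, rigid ICP registration with signed surface-deviation
    mapping and distribution summaries, an Ogden hyperelastic model for
    ligament-graft stress-strain curves with nonlinear curve fitting, and a
    per-flexion-angle error-rate metric with cross-method ranking. A synthetic
    phantom generator with analytic ground truth makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
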