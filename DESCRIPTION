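Package: fabricmap
Title: Registration-Based Prediction of Trabecular Bone Fabric Tensors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts trabecular bone fabric tensors in clinical-resolution
    CT volumes of the proximal femur by deformable image registration against
    a femur atlas. Implements two-stage (affine plus cubic B-spline)
    intensity-based registration with normalized-correlation similarity and
    curvature regularization, a log-stretch deformation distance metric for
    atlas selection, mean-intercept-length (MIL) fabric extraction from
    high-resolution images, five finite-strain tensor mapping schemes
    (identity, global/local rotation, global/local full deformation),
    fabric-atlas averaging, femur morphology landmarks, and a leave-one-out
    evaluation scheme with tensor-norm, degree-of-anisotropy and
    principal-direction error metrics. Synthetic phantom generators provide
    paired low/high-resolution femur-like volumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Registration, BiomedicalInformatics
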