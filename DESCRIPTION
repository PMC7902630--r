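Package: cascadeseg
Title: Auto-Context Cascaded Orthogonal-Plane Segmentation of 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric binary segmentation by a three-stage auto-context cascade of
    orthogonal-plane (axial, coronal, sagittal) 2D encoder-decoder networks with
    largest-connected-component refinement between stages, aimed at small bright
    structures such as the bony labyrinth of the inner ear in micro-CT. Includes
    NIfTI/NRRD volume handling with spline resampling and training-set intensity
    normalisation; three 2D architectures (U-Net, residual U-Net and
    squeeze-and-excitation U-Net) with a self-contained training engine; a synthetic
    inner-ear phantom generator with intensity-confusable air-cell blobs; an eight-metric
    evaluation suite (Dice, Jaccard, accuracy, precision, recall, specificity, ROC AUC,
    3D Hausdorff distance) with exact paired Wilcoxon signed-rank comparison; and a
    specimen-level cross-validation and architecture-comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
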