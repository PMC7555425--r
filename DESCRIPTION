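Package: segqc
Title: Automated Quality Control Scoring for 3D Prostate Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free quality control for automated 3D prostate
    segmentations on T2-weighted MRI. Computes a composite reference quality
    score (rQS) from twelve region-wise segmentation metrics (Dice, absolute
    relative volume difference, 95th-percentile Hausdorff distance and average
    symmetric surface distance over the whole gland, apex and base), calibrated
    against a second-observer cohort with the observer mean anchored at 85 on a
    0-100 scale. Extracts a 321-entry radiomics feature vector (first-order,
    3D shape and five texture-matrix families at fixed bin width) from the
    segmented volume and fits a LASSO linear regression that estimates the
    quality score from features alone, with cross-validated penalty selection
    and Bland-Altman bias screening. Includes a synthetic phantom generator
    with graded mask perturbations so the full pipeline is testable without
    clinical data, plus NIfTI and MetaImage I/O and evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
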