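Package: mmseg
Title: Atlas-Guided Segmentation and ADC Quantification of Multiple
    Myeloma Lesions on Whole-Body Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic segmentation of multiple-myeloma bone lesions on
    whole-body diffusion-weighted MRI (WB-DWI). An atlas with pre-drawn organ
    and skeleton masks is propagated to each patient by multi-stage image
    registration (rigid, affine, B-spline free-form); normally hyperintense
    organs are removed and the lesion search is restricted to the skeleton
    and nearby areas. Candidate lesions are detected by quartile-outlier
    thresholding of the DWI intensity distribution, split into 3D connected
    components, and filtered against the mean psoas-muscle intensity on a
    rigidly co-registered T1-weighted volume. The package also computes
    apparent diffusion coefficient (ADC) maps from two b-values, per-lesion
    ADC histogram metrics and volumes, and lesion-level validation metrics
    (Dice, sensitivity, positive predictive value, intraclass correlation),
    and ships a synthetic whole-body phantom generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
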