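Package: lcpipe
Title: Automated Localization, Segmentation and Contrast-Ratio Analysis of
    the Locus Coeruleus in Neuromelanin-Sensitive MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated analysis pipeline for the locus coeruleus (LC)
    in neuromelanin-sensitive T1-weighted MRI. Provides iterative multi-scale
    landmark localization of the bilateral LC with a differentiable
    spatial-to-numerical coordinate head, patch-based volumetric LC
    segmentation trained against one or several expert raters (including
    intersection and random-switching multi-rater strategies), brainstem
    substructure segmentation, and automated contrast-ratio extraction using
    Voronoi-derived pontine reference regions. Ships a synthetic
    brainstem-phantom generator with simulated raters so every stage can be
    trained and validated against known ground truth, plus evaluation
    utilities (Dice, multi-rater Dice, false discovery rate, localization
    error, ICC(2,1), Welch t test) and a stratified nested cross-validation
    planner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
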