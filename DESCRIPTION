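Package: tilquant
Title: Automated Quantification of Tumor-Infiltrating Lymphocytes from
    H&E-Stained Section Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying tumor-infiltrating
    lymphocytes (TILs) in haematoxylin-eosin stained tumor section images:
    colour-space transformation, Otsu thresholding, morphological opening and
    marker-controlled watershed segmentation of nuclei; extraction of a fixed
    43-feature morphological/intensity/texture/neighbourhood vector per
    nucleus; support-vector-machine classification into cancer cells,
    lymphocytes and stromal cells; and computation of the slide-level TIL
    proportion (lymphocytes over all detected cells). Includes a synthetic
    H&E-like image generator with ground-truth nuclei, a proportional-hazards
    cohort simulator, classifier validation tools (stratified
    cross-validation, concordance with manual counts, Jonckheere-Terpstra
    trend test), nonparametric cohort statistics, and Kaplan-Meier / Cox
    survival analyses of TIL proportion as a prognostic biomarker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    survival,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
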