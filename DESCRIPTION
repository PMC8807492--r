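Package: stromatex
Title: Per-Pixel Haralick Texture Maps and Tumor-Stroma Classification for MR Microscopy
Version: 0.1.0
Authors@R: person("stromatex", "developers", role = c("aut", "cre"),
    email = "stromatex@example.org")
Description: An end-to-end pipeline linking ex vivo MR-microscopy radiomics to
    histopathology in high-grade serous ovarian cancer. Implements IBSI-style
    preprocessing (denoising, multiplicative bias-field correction, isotropic
    resampling, mean +/- 3 sd intensity outlier filtering), per-pixel gray-level
    co-occurrence matrices with 13 Haralick feature maps at 64 gray levels,
    stromal-proportion maps from tumor/stroma label rasters, binned Pearson
    association between texture and stromal proportion, and a balanced
    support-vector-machine pixel classifier producing stroma-rich/stroma-poor
    segmentation maps. Ships a synthetic phantom generator with paired
    ground-truth label maps so the whole chain is testable without external
    data, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
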