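Package: gliorad
Title: Multimodality MRI Radiomics for Glioma Necrosis versus Recurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end radiomics pipeline for classifying radiation
    necrosis versus tumor recurrence in gliomas from registered
    multimodality MRI (T1, T1C, T2, FLAIR) with a tumor mask. Provides
    handcrafted feature extraction (nontexture shape features plus a
    parameter grid of GLCM, GLRLM, GLSZM and NGTDM texture statistics over
    wavelet band-pass filtering, isotropic resampling and gray-level
    quantization), a pluggable deep-feature extraction contract with a
    deterministic stub backend, Spearman univariate screening with
    Bonferroni correction, gain-equation feature reduction driven by the
    maximal information coefficient, imbalance-adjusted bootstrap
    resampling, 0.632+ bootstrap AUC stepwise forward model selection,
    bootstrap-averaged logistic model construction, and ensemble
    evaluation with paired comparisons. Includes synthetic phantom and
    feature-table generators so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
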