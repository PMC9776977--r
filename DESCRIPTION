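Package: adcradiomics
Title: Local First-Order Radiomics of Prostate ADC Maps with a Linear SVM Signature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes sliding-window first-order parametric maps on apparent
    diffusion coefficient (ADC) images of the prostate, summarises each lesion
    into a 132-dimensional radiomic feature vector, performs two-stage feature
    selection (weighted LASSO screen followed by an exhaustive four-feature
    linear support vector machine search ranked by Wilcoxon significance and
    informedness), trains and calibrates an augmented linear-SVM signature
    predicting clinically significant prostate cancer (Gleason Grade group
    >= 3), and runs the Gleason-group similarity analysis (Kruskal-Wallis,
    one-tail Wilcoxon, Ansari-Bradley after median removal). Includes a
    synthetic ADC cohort generator so the whole pipeline is testable without
    patient data, plus minimal NIfTI-1, 16-bit TIFF, DICOM and PNG mask I/O.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    quadprog,
    png,
    jsonlite,
    yaml,
    ggplot2,
    rlang,
    Rcpp,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
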