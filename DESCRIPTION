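Package: voipredict
Title: Seizure-Outcome Prediction from Multimodal Neuroimaging of the
    Surgical Target Volume
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts post-surgical seizure outcome (Engel class I
    seizure-free versus class II-IV recurrence) from co-registered
    multimodal neuroimaging (T1 MRI, FDG-PET, CT) of the resected target
    volume of interest. The pipeline crops the minimum circumscribed cube
    around the surgical mask, resamples it to a 64x64x64 grid, applies
    mask-based attention, extracts nine canonical 2.5-D views, computes
    512-dimensional deep features per view with a ResNet-34 backbone
    (pretrainable on a labelled grayscale image corpus), fuses
    per-modality feature kernels with a multi-kernel support vector
    machine on precomputed kernels, and evaluates with leave-one-out
    cross-validation, ROC/AUC and paired DeLong tests. Includes a
    synthetic multimodal lesion-phantom generator so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    kernlab,
    jsonlite,
    digest,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
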