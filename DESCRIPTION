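Package: ramanAD
Title: Spectral Barcoding and Classification of Alzheimer's Disease from CSF Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for droplet-deposition Raman spectroscopy of cerebrospinal
    fluid: spectral preprocessing (background subtraction, cosmic-ray spike
    removal, Haar-wavelet denoising, polynomial baseline and rubberband
    anchoring, vector normalisation, PCA outlier screening), per-wavenumber
    Mann-Whitney "spectral barcode" biomarker extraction with region-area
    features, patient-stratified classification with bagged decision trees
    and linear support-vector machines including per-patient score
    aggregation and ROC evaluation, surrogate-model and partial-dependence
    feature importance, and age/sex-adjusted partial correlation of spectral
    features with CSF ATN biomarkers under Benjamini-Hochberg FDR control.
    Includes a seeded synthetic-cohort generator emulating the statistical
    structure of a clinical CSF Raman study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    randomForest,
    rpart,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
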