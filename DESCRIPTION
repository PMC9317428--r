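Package: mpMRIpcr
Title: Multiparametric MRI Biomarkers and Machine Learning for Predicting
    Pathological Complete Response to Neoadjuvant Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for predicting pathological complete response
    (pCR) to neoadjuvant chemotherapy in breast cancer from pre-treatment
    multiparametric MRI. Provides a synthetic mpMRI cohort generator with
    known voxel-wise ground truth, semi-quantitative DCE-MRI perfusion
    biomarkers (iAUC60, initial slope, peak enhancement, time-to-peak),
    mono-exponential ADC and segmented bi-exponential IVIM diffusion fitting,
    IBSI-style first-order and texture radiomics (GLCM, GLRLM, GLSZM, NGTDM),
    two-step variance/correlation feature selection with per-feature group
    statistics, and a balanced leave-one-out cross-validation comparison of
    ten classifier families over imaging, clinical and combined feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    rpart,
    nnet,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071
Config/testthat/edition: 3
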