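# mpMRIpcr

Predicting pathological complete response (pCR) to neoadjuvant
chemotherapy in breast cancer from pre-treatment multiparametric MRI.

Only a minority of breast-cancer patients achieve pCR after neoadjuvant
chemotherapy, yet pCR is one of the strongest surrogate markers of
outcome. This package implements, as a tested and reusable R pipeline,
the analysis pattern used to ask whether imaging biomarkers can predict
pCR before treatment starts:

* **Perfusion (DCE-MRI):** per-voxel semi-quantitative biomarkers from
  the contrast-concentration curve — initial area under the curve over
  the first 60 s (iAUC60), initial ascending slope, peak enhancement,
  and time-to-peak (TTP);
* **Diffusion (multi-b DWI):** the mono-exponential ADC and the
  bi-exponential intravoxel-incoherent-motion (IVIM) fit
  `S(b) = S0·[f·exp(−b·D*) + (1−f)·exp(−b·D)]`, giving pure diffusion D,
  pseudo-diffusion D\* and vascular fraction f;
* **Radiomics:** IBSI-style first-order and texture features (GLCM,
  GLRLM, GLSZM, NGTDM) on the ADC and iAUC60 maps — 251 imaging features
  per patient with the default panel;
* **Feature selection and statistics:** two-step selection (variance ≤
  0.1 eliminated, then |r| > 0.8 pairs resolved in favour of the
  higher-variance member) and per-feature pooled t-tests between
  responders and non-responders;
* **Model comparison:** after balancing by random undersampling, ten
  classifier families (k-NN, decision tree, random forest, AdaBoost,
  gradient boosting, Gaussian naive Bayes, LDA, QDA, MLP, logistic
  regression) under leave-one-out cross-validation, over imaging-only,
  clinical-only and combined feature sets, with confusion matrices and
  accuracy/sensitivity/specificity/error-rate per cell.

Because the cohort this analysis pattern comes from is not publicly
deposited, the package also ships a **synthetic mpMRI cohort generator**
with known voxel-wise ground truth (gamma-variate DCE uptake, IVIM DWI
signals with Rician noise, spherical tumour masks, group-calibrated
parameter distributions and weakly informative binary clinical
covariates), so that every stage is testable end-to-end without any
download. See the methods vignette
(`vignettes/mpmri-pcr-methods.Rmd`) for the models, calibrations and
design decisions.

## Worked example

```r
library(mpMRIpcr)

spec <- cohort_spec(n_responders = 12, n_nonresponders = 12,
                    roi_radius = 4, seed = 42)
res <- run_pcr_pipeline(spec)

res$selection
#> <selection_result> 21 retained, 230 removed (136 low-variance, 94 correlated)

res$comparison
#> <comparison_report> 30 grid cells over 1 balancing seed(s)
#>   best clinical  knn       accuracy  66.7%
#>   best combined  adaboost  accuracy  79.2%
#>   best imaging   adaboost  accuracy  79.2%

head(significant_features(res$group_comparison)[,
  c("feature", "mean_pcr", "sd_pcr", "mean_non_pcr", "sd_non_pcr", "p")], 4)
#>               feature  mean_pcr   sd_pcr mean_non_pcr sd_non_pcr        p
#>          ADC_fo_Range  0.000667 0.000126      0.00101   0.000156 6.48e-06
#>  ADC_glcm_Correlation  0.383722 0.202168      0.04431   0.028030 8.54e-06
#>       ADC_fo_Skewness -0.305365 0.342063     -0.99140   0.261988 1.53e-05
#>         ADC_glcm_Imc2  0.634676 0.131923      0.42759   0.050607 4.37e-05
```

The pipeline generated a balanced 24-patient synthetic cohort, extracted
the 251 imaging features per patient, kept 21 after the two-step
selection, and ran the full 3-configurations × 10-classifiers
leave-one-out grid. On this seed the best combined-configuration
classifier reaches 79.2% accuracy against 66.7% for the best
clinical-only model — the qualitative ordering (imaging adds predictive
value over clinical variables alone) that the pipeline is designed to
probe. The significant-feature table lists group means (SD) and
unadjusted pooled-t p-values; here the separation is carried by ADC
texture and histogram features, consistent with the generator's
smoother-ADC-in-responders calibration.

Lower-level entry points: `generate_cohort()` / `write_cohort()` /
`read_patient()` for data, `perfusion_maps()` and `diffusion_maps()` for
voxel-wise biomarkers, `extract_radiomics()` for texture features,
`select_features()` / `compare_groups()` for the feature stage, and
`balance_cohort()` / `loocv()` / `compare_configurations()` for the
model stage.

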