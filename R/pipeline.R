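#' Run the full pCR-prediction pipeline on a synthetic cohort
#'
#' simulate -> extract -> select -> compare: generates the cohort, extracts
#' the 251 imaging features per patient, runs the per-feature group
#' comparison on the whole cohort, applies the two-step feature selection
#' to the imaging features, and compares the ten classifier families over
#' the imaging-only, clinical-only and combined configurations with
#' balanced leave-one-out cross-validation.
#'
#' @param spec a [cohort_spec()].
#' @param balance_seeds undersampling seed(s) for [compare_configurations()].
#' @param var_threshold,cor_threshold,scaling feature-selection settings,
#'   see [select_features()].
#' @param config a [radiomics_config()].
#' @param progress print per-stage progress (default `FALSE`).
#' @return list with `cohort_manifest`, `features` (the full
#'   [assemble_feature_table()]), `group_comparison`, `selection`,
#'   `tables` (the three model views after selection) and `comparison`
#'   (the [compare_configurations()] report).
#' @export
run_pcr_pipeline <- function(spec, balance_seeds = 1L,
                             var_threshold = 0.1, cor_threshold = 0.8,
                             scaling = "raw",
                             config = radiomics_config(),
                             progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  say("generating cohort (%d patients)...",
      spec$n_responders + spec$n_nonresponders)
  cohort <- generate_cohort(spec)
  manifest <- attr(cohort, "manifest")

  say("extracting imaging features...")
  imaging <- t(vapply(cohort, extract_features, numeric(251L),
                      config = config))
  rownames(imaging) <- manifest$patient_id
  clinical <- as.matrix(manifest[, rownames(spec$clinical_prob)])
  rownames(clinical) <- manifest$patient_id

  table <- assemble_feature_table(imaging, clinical, manifest$pcr)

  say("group statistics and feature selection...")
  groupcmp <- compare_groups(imaging, manifest$pcr)
  sel <- select_features(imaging, var_threshold, cor_threshold,
                         scaling = scaling)
  img_sel <- imaging[, sel$retained, drop = FALSE]
  tables <- list(imaging = img_sel,
                 clinical = clinical,
                 combined = cbind(img_sel, clinical))

  say("classifier comparison (%d seed(s) x 3 configurations x %d classifiers)...",
      length(balance_seeds), length(classifier_ids()))
  cmp <- compare_configurations(tables, manifest$pcr,
                                balance_seeds = balance_seeds)
  list(cohort_manifest = manifest, features = table,
       group_comparison = groupcmp, selection = sel,
       tables = tables, comparison = cmp)
}
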