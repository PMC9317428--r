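# On-disk layout: one NIfTI-1 volume per DCE dynamic / DWI b-value per
# patient, a JSON sidecar with the timing and diffusion metadata, the
# tumour mask as NIfTI, and a cohort-level manifest CSV.

#' Write a synthetic cohort to disk
#'
#' Lays out each patient as a directory of NIfTI-1 volumes (`dce_dyn%02d`,
#' `dwi_b%04d`, `mask`) with a JSON sidecar (`acquisition.json`: dynamic
#' times, injection time, b-values, voxel spacing), plus `manifest.csv`
#' (patient id, pCR label, clinical flags) and `truth.csv` (patient-level
#' ground-truth summaries) at the cohort root.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stop_if(!inherits(cohort, "mpmri_cohort"), "not an mpmri_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    sp <- p$dce$spacing
    for (k in seq_along(p$dce$times)) {
      RNifti::writeNifti(
        RNifti::asNifti(p$dce$intensities[, , , k], pixdim = sp),
        file.path(pd, sprintf("dce_dyn%02d.nii.gz", k)))
    }
    for (k in seq_along(p$dwi$bvalues)) {
      RNifti::writeNifti(
        RNifti::asNifti(p$dwi$volumes[[k]], pixdim = sp),
        file.path(pd, sprintf("dwi_b%04d.nii.gz", p$dwi$bvalues[k])))
    }
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(p$mask), dim(p$mask)),
                                       pixdim = sp),
                       file.path(pd, "mask.nii.gz"))
    jsonlite::write_json(
      list(times = p$dce$times, injection_time = p$dce$injection_time,
           bvalues = p$dwi$bvalues, spacing = sp),
      file.path(pd, "acquisition.json"),
      auto_unbox = TRUE, digits = NA)
  }
  manifest <- attr(cohort, "manifest")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  truth <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$id, pcr = p$pcr,
               ttp_center = p$truth$ttp_center,
               dstar_sd = p$truth$dstar_sd,
               d_median = stats::median(p$truth$d[p$mask]),
               f_median = stats::median(p$truth$f[p$mask]))
  }))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read one patient back from a cohort directory
#'
#' Inverse of the [write_cohort()] layout for a single patient directory.
#'
#' @param patient_dir path to one patient's directory.
#' @return list with `dce` (a [dce_series()]), `dwi` (a [dwi_series()])
#'   and `mask` (logical array).
#' @export
read_patient <- function(patient_dir) {
  meta <- jsonlite::read_json(file.path(patient_dir, "acquisition.json"),
                              simplifyVector = TRUE)
  plain <- function(v) array(as.numeric(v), dim(v))
  vols <- lapply(seq_along(meta$times), function(k) {
    plain(RNifti::readNifti(
      file.path(patient_dir, sprintf("dce_dyn%02d.nii.gz", k))))
  })
  arr <- array(0, c(dim(vols[[1L]]), length(vols)))
  for (k in seq_along(vols)) arr[, , , k] <- vols[[k]]
  dce <- dce_series(arr, meta$times, meta$injection_time, meta$spacing)
  dvols <- lapply(meta$bvalues, function(b) {
    plain(RNifti::readNifti(
      file.path(patient_dir, sprintf("dwi_b%04d.nii.gz", b))))
  })
  dwi <- dwi_series(dvols, meta$bvalues, meta$spacing)
  mask <- plain(RNifti::readNifti(file.path(patient_dir, "mask.nii.gz"))) > 0
  list(dce = dce, dwi = dwi, mask = mask)
}
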