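#' Specification of a synthetic mpMRI cohort
#'
#' Defines the study conditions for a simulated two-group (pCR vs non-pCR)
#' breast mpMRI cohort: group sizes, the group-level distributions of the
#' ground-truth perfusion/diffusion parameters, acquisition geometry and
#' timing, and noise levels. Group-valued arguments are length-2 vectors
#' named `c(pcr = , non_pcr = )`.
#'
#' Defaults encode the emulated study: 12 responders vs 46 non-responders;
#' time-to-peak calibrated to the published group means/SDs of the TTP 25th
#' percentile (187.47 (51.27) s in responders vs 237.67 (79.20) s in
#' non-responders); per-patient voxel-wise D* dispersion calibrated to the
#' published `D_star_std` of 0.006 (0.002) vs 0.007 (0.002) mm^2/s; and a
#' smoother ADC texture in responders (reduced tumour heterogeneity). The
#' DCE protocol keeps the published 40 s temporal resolution and contrast
#' injection 20 s after the end of the first (baseline) dynamic; the default
#' number of dynamics is 16 so that the sampled window contains the
#' calibrated TTP range (see the methods vignette).
#'
#' @param n_responders,n_nonresponders group sizes (counts >= 1).
#' @param ttp_mean,ttp_sd between-patient mean and SD of patient-level
#'   time-to-peak (s), per group.
#' @param ttp_within_sd within-patient (voxel-wise) TTP SD (s).
#' @param peak_mean,peak_sd voxel-wise peak concentration distribution (mM).
#' @param dstar_sd_mean,dstar_sd_sd between-patient distribution of the
#'   voxel-wise D* dispersion (mm^2/s), per group.
#' @param dstar_center centre of the voxel-wise D* distribution (mm^2/s).
#' @param d_mean,d_between_sd,d_within_sd pure-diffusion coefficient D:
#'   patient-level mean/SD and voxel-wise SD (mm^2/s).
#' @param f_mean,f_sd voxel-wise vascular fraction distribution (%).
#' @param texture_homogeneity spatial smoothness of the ADC map in [0, 1],
#'   per group; higher values give a more homogeneous texture.
#' @param snr_dwi DWI signal-to-noise ratio (Rician scale S0/snr); `Inf`
#'   for noiseless.
#' @param noise_dce additive Gaussian DCE noise SD (scanner intensity units;
#'   baseline signal is 100).
#' @param voxel_spacing voxel spacing in mm (length 3).
#' @param roi_radius tumour mask radius in voxels (>= 2).
#' @param n_dynamics,dt number of DCE dynamics and temporal resolution (s).
#' @param bvalues DWI b-values (s/mm^2); must include 0.
#' @param clinical_prob 4 x 2 matrix of probabilities for the four binary
#'   clinical flags (rows `age_over_40`, `premenopausal`, `stage_iii`,
#'   `grade_iii`; columns `pcr`, `non_pcr`).
#' @param seed integer seed making cohort generation deterministic.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders = 12L,
                        n_nonresponders = 46L,
                        ttp_mean = c(pcr = 187.47, non_pcr = 237.67),
                        ttp_sd = c(pcr = 51.27, non_pcr = 79.20),
                        ttp_within_sd = 30,
                        peak_mean = 1.0,
                        peak_sd = 0.15,
                        dstar_sd_mean = c(pcr = 0.006, non_pcr = 0.007),
                        dstar_sd_sd = c(pcr = 0.002, non_pcr = 0.002),
                        dstar_center = 0.020,
                        d_mean = 1.1e-3,
                        d_between_sd = 1.0e-4,
                        d_within_sd = 1.5e-4,
                        f_mean = 10,
                        f_sd = 2,
                        texture_homogeneity = c(pcr = 0.85, non_pcr = 0.25),
                        snr_dwi = 50,
                        noise_dce = 1,
                        voxel_spacing = c(1, 1, 1),
                        roi_radius = 5L,
                        n_dynamics = 16L,
                        dt = 40,
                        bvalues = c(0, 150, 400, 1000),
                        clinical_prob = default_clinical_prob(),
                        seed = 1L) {
  grp <- function(x, nm) {
    x <- if (length(x) == 1L) c(pcr = unname(x), non_pcr = unname(x)) else x
    stop_if(!all(c("pcr", "non_pcr") %in% names(x)),
            sprintf("`%s` must be named c(pcr=, non_pcr=)", nm))
    x[c("pcr", "non_pcr")]
  }
  stop_if(!is_count(n_responders) || !is_count(n_nonresponders),
          "group sizes must be counts >= 1")
  stop_if(any(c(ttp_sd, ttp_within_sd, dstar_sd_sd, peak_sd, f_sd) < 0),
          "SDs must be >= 0")
  stop_if(!is.finite(snr_dwi) && !is.infinite(snr_dwi) || snr_dwi <= 0,
          "snr_dwi must be > 0")
  stop_if(noise_dce < 0, "noise_dce must be >= 0")
  stop_if(!is_count(roi_radius) || roi_radius < 2, "roi_radius must be >= 2")
  stop_if(dt <= 0, "non-positive temporal resolution")
  stop_if(!is_count(n_dynamics) || n_dynamics < 3, "need >= 3 dynamics")
  stop_if(any(bvalues < 0), "negative b-value")
  stop_if(!is.matrix(clinical_prob) || !identical(dim(clinical_prob), c(4L, 2L)),
          "clinical_prob must be a 4 x 2 matrix")
  spec <- list(
    n_responders = as.integer(n_responders),
    n_nonresponders = as.integer(n_nonresponders),
    ttp_mean = grp(ttp_mean, "ttp_mean"), ttp_sd = grp(ttp_sd, "ttp_sd"),
    ttp_within_sd = ttp_within_sd,
    peak_mean = peak_mean, peak_sd = peak_sd,
    dstar_sd_mean = grp(dstar_sd_mean, "dstar_sd_mean"),
    dstar_sd_sd = grp(dstar_sd_sd, "dstar_sd_sd"),
    dstar_center = dstar_center,
    d_mean = d_mean, d_between_sd = d_between_sd, d_within_sd = d_within_sd,
    f_mean = f_mean, f_sd = f_sd,
    texture_homogeneity = grp(texture_homogeneity, "texture_homogeneity"),
    snr_dwi = snr_dwi, noise_dce = noise_dce,
    voxel_spacing = voxel_spacing, roi_radius = as.integer(roi_radius),
    n_dynamics = as.integer(n_dynamics), dt = dt,
    bvalues = sort(bvalues),
    clinical_prob = clinical_prob,
    seed = as.integer(seed))
  spec$times <- spec$dt * seq_len(spec$n_dynamics)     # timestamp = end of dynamic
  spec$injection_time <- spec$dt + 20                  # 20 s after end of dynamic 1
  # TTP range representable inside the sampled window (relative to injection)
  comb <- spec$times - spec$injection_time
  spec$ttp_comb <- comb[comb > 0]
  stop_if(max(spec$ttp_mean) > max(spec$ttp_comb),
          "calibrated TTP means fall outside the acquisition window; ",
          "increase n_dynamics")
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d pCR + %d non-pCR patients, seed %d\n",
              x$n_responders, x$n_nonresponders, x$seed))
  cat(sprintf("  DCE: %d dynamics at %g s, injection at %g s; noise SD %g\n",
              x$n_dynamics, x$dt, x$injection_time, x$noise_dce))
  cat(sprintf("  DWI: b = %s; SNR %g\n", paste(x$bvalues, collapse = ", "),
              x$snr_dwi))
  cat(sprintf("  TTP mean (pcr/non): %.1f / %.1f s; D* dispersion: %.4f / %.4f\n",
              x$ttp_mean[1], x$ttp_mean[2], x$dstar_sd_mean[1], x$dstar_sd_mean[2]))
  invisible(x)
}

#' Default group-conditional probabilities of the clinical flags
#'
#' Mildly imbalanced between groups so that the clinical-only model is
#' weakly informative; the exact values are configuration, not a claim
#' about breast-cancer epidemiology.
#' @return 4 x 2 numeric matrix (flags x groups).
#' @export
default_clinical_prob <- function() {
  m <- rbind(age_over_40   = c(0.70, 0.80),
             premenopausal = c(0.50, 0.35),
             stage_iii     = c(0.40, 0.55),
             grade_iii     = c(0.50, 0.30))
  colnames(m) <- c("pcr", "non_pcr")
  m
}

#' Gamma-variate uptake curve
#'
#' Smooth unimodal bolus-uptake model used as the DCE forward model:
#' zero before `onset`, then
#' `peak * tau^alpha * exp(alpha * (1 - tau))` with
#' `tau = (t - onset) / (ttp - onset)`. Its analytic maximum is at
#' `t = ttp` with value `peak` (times measured from injection start).
#'
#' @param t time(s) since injection start (s); vectorised.
#' @param peak maximum concentration (mM).
#' @param ttp time of the maximum (s since injection).
#' @param onset contrast-arrival delay (s since injection, < `ttp`).
#' @param alpha shape parameter (> 0); larger values sharpen the bolus.
#' @return concentration value(s) in mM.
#' @export
gamma_variate <- function(t, peak, ttp, onset = 0, alpha = 3) {
  stop_if(any(ttp <= onset), "ttp must exceed onset")
  tau <- (t - onset) / (ttp - onset)
  out <- ifelse(tau > 0, peak * tau^alpha * exp(alpha * (1 - tau)), 0)
  out
}

# Draw per-voxel ground-truth parameter fields for one patient.
# Returns full-grid arrays; the tumour mask is applied downstream.
draw_patient_params <- function(spec, group = c("pcr", "non_pcr")) {
  group <- match.arg(group)
  dim3 <- rep(2L * (spec$roi_radius + 3L) + 1L, 3L)
  nv <- prod(dim3)
  window <- max(spec$ttp_comb)

  ttp_center <- rnorm_trunc(1L, spec$ttp_mean[group], spec$ttp_sd[group],
                            lower = min(spec$ttp_comb) + spec$dt,
                            upper = window - spec$dt)
  ttp_vox <- rnorm_trunc(nv, ttp_center, spec$ttp_within_sd,
                         lower = min(spec$ttp_comb), upper = window)
  # Truth TTP is defined at the sampling resolution: snap to the
  # post-injection sampling comb (see methods vignette).
  snap <- function(x) spec$ttp_comb[
    pmax(1L, pmin(length(spec$ttp_comb),
                  round((x - spec$ttp_comb[1L]) / spec$dt) + 1L))]
  ttp_vox <- array(snap(ttp_vox), dim3)

  peak_vox <- array(rnorm_trunc(nv, spec$peak_mean, spec$peak_sd, lower = 0.2),
                    dim3)

  # Pure-diffusion field with group-dependent spatial smoothness and a
  # negative skew (necrotic/low-ADC pockets); smoother in responders.
  h <- spec$texture_homogeneity[group]
  z <- smooth_gaussian3d(array(stats::rnorm(nv), dim3), sigma = 2 * h)
  z <- (z - mean(z)) / stats::sd(z)
  z <- z - 0.4 * (z^2 - 1)                  # negative third moment
  z <- (z - mean(z)) / stats::sd(z)
  d_patient <- rnorm_trunc(1L, spec$d_mean, spec$d_between_sd, lower = 4e-4)
  d_vox <- d_patient + spec$d_within_sd * z
  d_vox[d_vox < 2e-4] <- 2e-4

  dstar_sd <- rnorm_trunc(1L, spec$dstar_sd_mean[group],
                          spec$dstar_sd_sd[group], lower = 5e-4)
  # pseudo-diffusion stays well above D (fast compartment is faster; values
  # overlapping D are not physically meaningful IVIM)
  dstar_vox <- array(rnorm_trunc(nv, spec$dstar_center, dstar_sd,
                                 lower = 8e-3, upper = 0.2), dim3)
  dstar_vox <- pmax(dstar_vox, d_vox + 2e-3)

  f_vox <- array(rnorm_trunc(nv, spec$f_mean, spec$f_sd, lower = 1, upper = 40),
                 dim3)

  list(group = group, dim = dim3,
       ttp = ttp_vox, peak = peak_vox, onset = 0, alpha = 3,
       d = d_vox, dstar = dstar_vox, f = f_vox,
       ttp_center = ttp_center, dstar_sd = dstar_sd,
       s0_dce = 100, s0_dwi = 1000)
}

#' Generate a synthetic DCE series from ground-truth voxel parameters
#'
#' Samples the gamma-variate truth curve of every voxel at the acquisition
#' timestamps of `spec` and adds Gaussian noise. The continuous truth
#' (per-voxel peak/TTP/onset/shape) is returned alongside so that oracle
#' integration of the analytic curve is possible.
#'
#' @param spec a [cohort_spec()].
#' @param params per-voxel truth as produced by the cohort generator
#'   (arrays `ttp`, `peak`, scalars `onset`, `alpha`, `s0_dce`).
#' @param seed optional integer seed for the noise draw.
#' @param noise additive Gaussian noise SD; defaults to `spec$noise_dce`.
#' @return list with `series` (a [dce_series()]) and `truth` (the curve
#'   parameters).
#' @export
generate_dce <- function(spec, params, seed = NULL, noise = spec$noise_dce) {
  stop_if(spec$dt <= 0, "non-positive temporal resolution")
  window <- max(spec$times) - spec$injection_time
  stop_if(any(params$ttp <= 0) || any(params$ttp > window),
          "TTP outside the acquisition window")
  if (!is.null(seed)) set.seed(seed)
  dim3 <- dim(params$ttp)
  nt <- length(spec$times)
  arr <- array(0, c(dim3, nt))
  for (k in seq_len(nt)) {
    t_rel <- spec$times[k] - spec$injection_time
    conc <- gamma_variate(t_rel, params$peak, params$ttp,
                          onset = params$onset, alpha = params$alpha)
    s <- params$s0_dce * (1 + conc)
    if (noise > 0) s <- s + stats::rnorm(length(s), sd = noise)
    arr[, , , k] <- s
  }
  list(series = dce_series(arr, spec$times, spec$injection_time,
                           spec$voxel_spacing),
       truth = list(peak = params$peak, ttp = params$ttp,
                    onset = params$onset, alpha = params$alpha,
                    s0 = params$s0_dce))
}

#' Bi-exponential IVIM forward signal
#'
#' `S(b) = S0 * ((f/100) * exp(-b * dstar) + (1 - f/100) * exp(-b * d))`,
#' the intravoxel-incoherent-motion model with vascular fraction `f` in
#' percent.
#'
#' @param b b-value(s) (s/mm^2).
#' @param s0 signal at b = 0.
#' @param f vascular fraction (percent, 0-100).
#' @param d pure diffusion coefficient (mm^2/s).
#' @param dstar pseudo-diffusion coefficient (mm^2/s), must be >= `d`.
#' @return signal value(s).
#' @export
ivim_signal <- function(b, s0, f, d, dstar) {
  stop_if(any(b < 0), "negative b-value")
  stop_if(any(f < 0 | f > 100), "f must be in [0, 100] percent")
  stop_if(any(dstar < d), "dstar < d: the fast compartment must be faster")
  fr <- f / 100
  s0 * (fr * exp(-b * dstar) + (1 - fr) * exp(-b * d))
}

#' Generate a synthetic DWI series from ground-truth voxel parameters
#'
#' Evaluates the IVIM forward model at the b-values of `spec` and applies
#' Rician noise of scale `S0 / snr_dwi` (magnitude MRI).
#'
#' @inheritParams generate_dce
#' @param params per-voxel truth (arrays `f`, `d`, `dstar`, scalar `s0_dwi`).
#' @param snr signal-to-noise ratio; defaults to `spec$snr_dwi`, `Inf` for
#'   noiseless.
#' @return list with `series` (a [dwi_series()]) and `truth`.
#' @export
generate_dwi <- function(spec, params, seed = NULL, snr = spec$snr_dwi) {
  stop_if(any(spec$bvalues < 0), "negative b-value")
  stop_if(any(params$dstar < params$d),
          "dstar < d: the fast compartment must be faster")
  stop_if(any(params$f < 0 | params$f > 100), "f must be in [0, 100] percent")
  if (!is.null(seed)) set.seed(seed)
  sigma <- if (is.infinite(snr)) 0 else params$s0_dwi / snr
  vols <- lapply(spec$bvalues, function(b) {
    s <- ivim_signal(b, params$s0_dwi, params$f, params$d, params$dstar)
    if (sigma > 0) {
      n1 <- stats::rnorm(length(s), sd = sigma)
      n2 <- stats::rnorm(length(s), sd = sigma)
      s <- sqrt((s + n1)^2 + n2^2)
    }
    array(s, dim(params$d))
  })
  names(vols) <- paste0("b", spec$bvalues)
  list(series = dwi_series(vols, spec$bvalues, spec$voxel_spacing),
       truth = list(f = params$f, d = params$d, dstar = params$dstar,
                    s0 = params$s0_dwi))
}

# Draw the four binary clinical covariates for one patient.
draw_clinical <- function(spec, group) {
  p <- spec$clinical_prob[, if (group == "pcr") "pcr" else "non_pcr"]
  flags <- as.integer(stats::runif(4L) < p)
  names(flags) <- rownames(spec$clinical_prob)
  flags
}

#' Generate one synthetic patient
#'
#' @param spec a [cohort_spec()].
#' @param group `"pcr"` or `"non_pcr"`.
#' @param seed integer seed for this patient's draws.
#' @return list with elements `dce`, `dwi` (series), `mask` (logical 3D
#'   array), `truth` (voxel-wise parameter arrays), `clinical` (named
#'   binary vector) and `pcr` (0/1).
#' @export
generate_patient <- function(spec, group = c("pcr", "non_pcr"), seed = 1L) {
  group <- match.arg(group)
  set.seed(seed)
  params <- draw_patient_params(spec, group)
  mask <- sphere_mask(params$dim, spec$roi_radius)
  dce <- generate_dce(spec, params)
  dwi <- generate_dwi(spec, params)
  clinical <- draw_clinical(spec, group)
  list(dce = dce$series, dwi = dwi$series, mask = mask,
       truth = list(ttp = params$ttp, peak = params$peak,
                    onset = params$onset, alpha = params$alpha,
                    d = params$d, dstar = params$dstar, f = params$f,
                    s0_dce = params$s0_dce, s0_dwi = params$s0_dwi,
                    ttp_center = params$ttp_center,
                    dstar_sd = params$dstar_sd),
       clinical = clinical, pcr = as.integer(group == "pcr"))
}

#' Generate a full synthetic mpMRI cohort
#'
#' Deterministic given `spec$seed`: exactly `n_responders` patients are
#' labelled pCR, responders receive the shorter-TTP / smaller-D*-dispersion /
#' smoother-ADC-texture parameter distributions of the specification, and
#' clinical flags are drawn with group-conditional probabilities.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `mpmri_cohort`: a list of patients (see
#'   [generate_patient()]) with a `manifest` attribute (data frame with
#'   `patient_id`, `pcr`, clinical flags).
#' @export
generate_cohort <- function(spec) {
  stop_if(!inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  n <- spec$n_responders + spec$n_nonresponders
  groups <- c(rep("pcr", spec$n_responders),
              rep("non_pcr", spec$n_nonresponders))
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    patients[[i]] <- generate_patient(spec, groups[i], seed = seeds[i])
    patients[[i]]$id <- sprintf("P%03d", i)
  }
  names(patients) <- vapply(patients, `[[`, character(1), "id")
  manifest <- data.frame(
    patient_id = names(patients),
    pcr = vapply(patients, `[[`, integer(1), "pcr"),
    t(vapply(patients, `[[`, numeric(4), "clinical")),
    row.names = NULL, check.names = FALSE)
  structure(patients, manifest = manifest, spec = spec,
            class = "mpmri_cohort")
}

#' @export
print.mpmri_cohort <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("<mpmri_cohort> %d patients (%d pCR, %d non-pCR)\n",
              nrow(m), sum(m$pcr == 1), sum(m$pcr == 0)))
  invisible(x)
}

#' Parameter-level biomarker feature table
#'
#' Draws per-patient ground-truth voxel parameters (no image rendering, no
#' acquisition noise) and summarises them into the five ROI statistics per
#' biomarker, exactly as the imaging pipeline would on noiseless data. Used
#' for statistical-calibration studies (type-I error, power of the TTP p25
#' group comparison) where the quantity of interest is defined at the
#' parameter level and rendering thousands of volumes would only add
#' noiseless plumbing.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return data frame: `patient_id`, `pcr`, then `<biomarker>_<stat>`
#'   columns for biomarkers TTP, peak, D, D_star, f and stats mean, median,
#'   std, p25, p75.
#' @export
simulate_biomarker_table <- function(spec, seed = spec$seed) {
  n <- spec$n_responders + spec$n_nonresponders
  groups <- c(rep("pcr", spec$n_responders),
              rep("non_pcr", spec$n_nonresponders))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    params <- draw_patient_params(spec, groups[i])
    mask <- sphere_mask(params$dim, spec$roi_radius)
    stats_of <- function(v) roi_statistics(array(v, params$dim), mask)
    feats <- c(TTP = stats_of(params$ttp), peak = stats_of(params$peak),
               D = stats_of(params$d), D_star = stats_of(params$dstar),
               f = stats_of(params$f))
    names(feats) <- sub("\\.", "_", names(feats))
    rows[[i]] <- feats
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                   pcr = as.integer(groups == "pcr")),
        out)
}
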