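#' Convert DCE signal to a concentration proxy
#'
#' Relative-enhancement conversion
#' `c(t) = relaxivity_scale * (S(t) - S0) / S0`, with the per-voxel
#' pre-contrast baseline `S0` estimated as the mean over all pre-injection
#' dynamics. Voxels with non-positive baseline are flagged invalid and
#' excluded from downstream maps. The semi-quantitative biomarker shapes
#' (TTP, slope ratios) are invariant to `relaxivity_scale`.
#'
#' @param series a [dce_series()].
#' @param relaxivity_scale multiplicative constant mapping relative
#'   enhancement to the concentration proxy (mM per unit enhancement;
#'   default 1).
#' @return An object of class `concentration_series`: list with `values`
#'   (4D array, mM), `times`, `injection_time`, `spacing` and `valid`
#'   (logical 3D array, FALSE where the baseline was non-positive).
#' @export
signal_to_concentration <- function(series, relaxivity_scale = 1) {
  stop_if(!inherits(series, "dce_series"), "`series` must be a dce_series")
  pre <- which(series$times < series$injection_time)
  nt <- length(series$times)
  s <- series$intensities
  s0 <- apply(s[, , , pre, drop = FALSE], 1:3, mean)
  valid <- is.finite(s0) & s0 > 0
  vals <- array(NA_real_, dim(s))
  s0safe <- ifelse(valid, s0, NA_real_)
  for (k in seq_len(nt)) {
    vals[, , , k] <- relaxivity_scale * (s[, , , k] - s0safe) / s0safe
  }
  structure(list(values = vals, times = series$times,
                 injection_time = series$injection_time,
                 spacing = series$spacing, valid = valid),
            class = "concentration_series")
}

# Indices of post-injection samples (injection instant included).
post_injection_idx <- function(times, injection_time) {
  idx <- which(times >= injection_time)
  stop_if(length(idx) == 0L, "empty post-injection window")
  idx
}

#' Peak enhancement of a concentration curve
#'
#' Maximum of the concentration curve over the post-injection samples.
#'
#' @param curve numeric vector, concentration per dynamic (mM).
#' @param times acquisition timestamps (s), one per sample.
#' @param injection_time injection start (s, same clock as `times`).
#' @return peak concentration (mM).
#' @export
compute_peak <- function(curve, times, injection_time) {
  stop_if(any(!is.finite(curve)), "curve must be finite")
  idx <- post_injection_idx(times, injection_time)
  max(curve[idx])
}

#' Time-to-peak of a concentration curve
#'
#' Time, measured from injection start, of the first post-injection sample
#' attaining the curve maximum (plateaus resolve to first attainment).
#'
#' @inheritParams compute_peak
#' @return time-to-peak in seconds.
#' @export
compute_ttp <- function(curve, times, injection_time) {
  stop_if(any(!is.finite(curve)), "curve must be finite")
  idx <- post_injection_idx(times, injection_time)
  post <- curve[idx]
  times[idx][which.max(post)] - injection_time
}

#' Initial area under the concentration curve over 60 s (iAUC60)
#'
#' Trapezoidal integral of the concentration curve from injection start to
#' 60 s after injection, with linear interpolation of the curve at both
#' window endpoints when they fall between samples.
#'
#' @inheritParams compute_peak
#' @param window integration window length (s, default 60).
#' @return integral in mM*s.
#' @export
compute_iauc60 <- function(curve, times, injection_time, window = 60) {
  stop_if(any(!is.finite(curve)), "curve must be finite")
  t_end <- injection_time + window
  stop_if(max(times) < t_end,
          sprintf("acquisition does not cover the integration window (need t = %g s)",
                  t_end))
  stop_if(min(times) > injection_time,
          "no sample at or before injection; cannot anchor the window")
  t0 <- injection_time
  inside <- times > t0 & times < t_end
  nodes <- c(t0, times[inside], t_end)
  vals <- stats::approx(times, curve, xout = nodes)$y
  sum(diff(nodes) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

#' Initial ascending slope of a concentration curve
#'
#' Maximum forward finite-difference slope between consecutive samples from
#' contrast onset (first post-injection sample exceeding `onset_frac` of
#' the peak) up to and including the peak sample. A flat zero curve has
#' slope 0; when the onset sample is already the peak the single available
#' pre-peak interval is used.
#'
#' @inheritParams compute_peak
#' @param onset_frac onset threshold as a fraction of the peak (default
#'   0.05).
#' @return slope in mM/s.
#' @export
compute_initial_slope <- function(curve, times, injection_time,
                                  onset_frac = 0.05) {
  stop_if(any(!is.finite(curve)), "curve must be finite")
  idx <- post_injection_idx(times, injection_time)
  # keep the last pre-injection sample so a peak at the first post-injection
  # sample still has one usable pre-peak interval
  pre <- which(times < injection_time)
  if (length(pre)) idx <- c(max(pre), idx)
  win <- curve[idx]
  twin <- times[idx]
  pk <- max(win[times[idx] >= injection_time])
  if (pk <= 0) return(0)
  i_peak <- which.max(win)
  i_on <- which(win > onset_frac * pk)[1L]
  if (is.na(i_on)) return(0)
  lo <- if (i_on < i_peak) i_on else max(1L, i_peak - 1L)
  if (lo == i_peak) return(0)   # peak at the very first sample, no interval
  d <- diff(win[lo:i_peak]) / diff(twin[lo:i_peak])
  max(d)
}

#' Voxel-wise semi-quantitative perfusion maps
#'
#' Computes iAUC60, initial slope, peak and time-to-peak at every valid
#' voxel of the tumour mask, after converting the DCE signal to a
#' concentration proxy.
#'
#' @param series a [dce_series()].
#' @param mask logical 3D array on the same grid.
#' @param relaxivity_scale see [signal_to_concentration()].
#' @param onset_frac see [compute_initial_slope()].
#' @return An object of class `perfusion_maps`: list of 3D arrays
#'   `iauc60` (mM*s), `initial_slope` (mM/s), `peak` (mM), `ttp` (s), all
#'   `NA` outside the valid masked voxels, plus `mask`, `valid` and
#'   `n_invalid`.
#' @export
perfusion_maps <- function(series, mask, relaxivity_scale = 1,
                           onset_frac = 0.05) {
  stop_if(!identical(dim(series$intensities)[1:3], dim(mask)),
          "mask and series are on different grids")
  stop_if(!any(mask), "empty mask")
  conc <- signal_to_concentration(series, relaxivity_scale)
  valid <- mask & conc$valid
  n_invalid <- sum(mask & !conc$valid)
  stop_if(!any(valid), "all masked voxels invalid (non-positive baseline)")

  nt <- length(conc$times)
  cm <- matrix(conc$values, ncol = nt)[which(valid), , drop = FALSE]
  times <- conc$times
  inj <- conc$injection_time
  pidx <- post_injection_idx(times, inj)
  post <- cm[, pidx, drop = FALSE]
  tpost <- times[pidx]

  pk <- apply(post, 1L, max)
  ttp <- tpost[apply(post, 1L, which.max)] - inj
  iauc <- apply(cm, 1L, compute_iauc60, times = times, injection_time = inj)
  slope <- apply(cm, 1L, compute_initial_slope, times = times,
                 injection_time = inj, onset_frac = onset_frac)

  put <- function(v) {
    a <- array(NA_real_, dim(mask))
    a[which(valid)] <- v
    a
  }
  structure(list(iauc60 = put(iauc), initial_slope = put(slope),
                 peak = put(pk), ttp = put(ttp),
                 mask = mask, valid = valid, n_invalid = n_invalid),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("<perfusion_maps> %d masked voxels (%d invalid)\n",
              sum(x$mask), x$n_invalid))
  invisible(x)
}
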