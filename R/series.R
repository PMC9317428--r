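#' DCE-MRI dynamic series
#'
#' Container for a 4D dynamic contrast-enhanced acquisition: one 3D volume
#' per dynamic, the acquisition timestamp of each dynamic (seconds, strictly
#' increasing), and the time at which contrast injection started. At least
#' one dynamic must precede the injection so a per-voxel pre-contrast
#' baseline can be estimated.
#'
#' @param intensities 4D numeric array (x, y, z, dynamic) in arbitrary
#'   scanner units.
#' @param times numeric vector of acquisition timestamps (s), one per
#'   dynamic, strictly increasing.
#' @param injection_time time (s, same clock as `times`) at which contrast
#'   injection started.
#' @param spacing voxel spacing in mm (length 3).
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(intensities, times, injection_time, spacing = c(1, 1, 1)) {
  stop_if(length(dim(intensities)) != 4L, "`intensities` must be a 4D array")
  stop_if(length(times) != dim(intensities)[4L],
          "`times` must have one entry per dynamic")
  stop_if(length(times) < 3L, "a DCE series needs at least 3 dynamics")
  stop_if(any(diff(times) <= 0), "`times` must be strictly increasing")
  stop_if(!is.finite(injection_time), "`injection_time` must be finite")
  stop_if(!any(times < injection_time),
          "at least one pre-injection dynamic is required")
  stop_if(length(spacing) != 3L || any(spacing <= 0), "invalid `spacing`")
  structure(
    list(intensities = intensities, times = as.numeric(times),
         injection_time = as.numeric(injection_time),
         spacing = as.numeric(spacing)),
    class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<dce_series> %dx%dx%d grid, %d dynamics (t = %s s), injection at %g s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$times, 4), collapse = ", "), x$injection_time))
  invisible(x)
}

#' Multi-b-value diffusion-weighted series
#'
#' Container for DWI volumes keyed by b-value. A b = 0 volume and at least
#' three distinct b-values are required; intensities must be non-negative
#' (magnitude MRI).
#'
#' @param volumes list of 3D arrays, one per b-value, all on the same grid.
#' @param bvalues numeric vector of b-values (s/mm^2), same length/order as
#'   `volumes`.
#' @param spacing voxel spacing in mm (length 3).
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(volumes, bvalues, spacing = c(1, 1, 1)) {
  stop_if(length(volumes) != length(bvalues),
          "`volumes` and `bvalues` must have the same length")
  stop_if(any(bvalues < 0), "negative b-value")
  stop_if(anyDuplicated(bvalues) > 0, "duplicated b-values")
  stop_if(!any(bvalues == 0), "a b = 0 volume is required")
  stop_if(length(bvalues) < 3L, "at least 3 distinct b-values are required")
  dims <- lapply(volumes, dim)
  stop_if(!all(vapply(dims, identical, logical(1), dims[[1L]])),
          "all volumes must share one grid")
  stop_if(any(vapply(volumes, function(v) any(v < 0, na.rm = TRUE), logical(1))),
          "DWI intensities must be non-negative")
  ord <- order(bvalues)
  structure(
    list(volumes = volumes[ord], bvalues = as.numeric(bvalues[ord]),
         spacing = as.numeric(spacing)),
    class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$volumes[[1L]])
  cat(sprintf("<dwi_series> %dx%dx%d grid, b = %s s/mm^2\n",
              d[1], d[2], d[3], paste(x$bvalues, collapse = ", ")))
  invisible(x)
}
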