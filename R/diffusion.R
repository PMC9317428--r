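#' Mono-exponential ADC fit
#'
#' Ordinary least-squares slope of `-log S(b)` versus `b` across all
#' b-values (Gaussian mono-exponential diffusion model). The fit is
#' invariant to positive rescaling of the signals. Voxels with any
#' non-positive signal are invalid and yield `NA`.
#'
#' @param signals numeric vector of signals, one per b-value.
#' @param bvalues numeric vector of b-values (s/mm^2).
#' @return ADC in mm^2/s, or `NA_real_` for an invalid voxel.
#' @export
fit_adc <- function(signals, bvalues) {
  stop_if(length(signals) != length(bvalues), "length mismatch")
  stop_if(length(signals) < 2L, "need >= 2 signals")
  if (any(!is.finite(signals)) || any(signals <= 0)) return(NA_real_)
  y <- log(signals)
  b <- bvalues
  -stats::cov(b, y) / stats::var(b)
}

# Weighted log-linear fit of S ~ S_int * exp(-b * D); weights ~ S^2
# (the standard correction for log-transformed magnitude data).
# Returns c(d, log_intercept).
loglin_fit <- function(signals, bvalues, weights = signals^2) {
  y <- log(signals)
  w <- weights / sum(weights)
  xb <- sum(w * bvalues)
  yb <- sum(w * y)
  sxx <- sum(w * (bvalues - xb)^2)
  slope <- sum(w * (bvalues - xb) * (y - yb)) / sxx
  c(d = -slope, log_intercept = yb - slope * xb)
}

#' Segmented bi-exponential IVIM fit
#'
#' Fits the intravoxel-incoherent-motion model
#' `S(b) = S0 * (f/100 * exp(-b*Dstar) + (1 - f/100) * exp(-b*D))`
#' by the segmented approach: (i) log-linear fit over `b >= b_threshold`
#' gives initial D and high-b intercept, (ii) `f = 1 - intercept / S(0)`,
#' (iii) the estimated fast compartment is subtracted and D and f are
#' re-fit by weighted log-linear least squares over all b-values (two
#' passes; see the methods vignette), and (iv) D* is estimated by bounded
#' one-dimensional least squares on the full curve with D and f fixed,
#' constrained to `D* >= D`.
#'
#' @inheritParams fit_adc
#' @param b_threshold perfusion-free threshold (s/mm^2, default 200):
#'   b-values at or above it are treated as diffusion-only.
#' @param refit logical; perform the perfusion-corrected re-fit of D and f
#'   over all b-values (default `TRUE`). With `FALSE` the plain two-point
#'   segmented estimates are returned.
#' @return named numeric vector `c(d, dstar, f)` with `d`, `dstar` in
#'   mm^2/s and `f` in percent, or all-`NA` for an invalid voxel.
#' @export
fit_ivim <- function(signals, bvalues, b_threshold = 200, refit = TRUE) {
  stop_if(length(signals) != length(bvalues), "length mismatch")
  invalid <- c(d = NA_real_, dstar = NA_real_, f = NA_real_)
  hi <- bvalues >= b_threshold
  lo <- !hi
  stop_if(sum(hi) < 2L || sum(lo) < 2L,
          "need >= 2 b-values on each side of b_threshold")
  s0 <- signals[bvalues == 0]
  stop_if(length(s0) != 1L, "exactly one b = 0 signal required")
  if (!is.finite(s0) || s0 <= 0) return(invalid)
  if (any(!is.finite(signals)) || any(signals[hi] <= 0)) return(invalid)

  ft <- loglin_fit(signals[hi], bvalues[hi])
  d <- max(ft[["d"]], 1e-6)
  f <- 1 - exp(ft[["log_intercept"]]) / s0
  f <- min(max(f, 0), 0.6)

  if (refit) {
    dstar <- fit_dstar(signals, bvalues, s0, d, f)
    for (pass in seq_len(8L)) {
      fast <- s0 * f * exp(-bvalues * dstar)
      sc <- signals - fast
      ok <- sc > 0
      if (sum(ok) < 2L) break
      ft <- loglin_fit(sc[ok], bvalues[ok])
      d_new <- ft[["d"]]
      if (!is.finite(d_new) || d_new <= 0) break
      converged <- abs(d_new - d) < 1e-9
      d <- d_new
      f <- min(max(1 - exp(ft[["log_intercept"]]) / s0, 0), 0.6)
      dstar <- fit_dstar(signals, bvalues, s0, d, f)
      if (converged) break
    }
    # joint bounded least-squares polish from the segmented solution; on
    # noiseless data this removes the residual bias the alternating scheme
    # can retain when D* sits close to D
    polished <- tryCatch({
      obj <- function(p) {
        if (p[3L] < p[1L]) return(1e12)   # finite barrier: D* >= D
        m <- s0 * (p[2L] * exp(-bvalues * p[3L]) +
                     (1 - p[2L]) * exp(-bvalues * p[1L]))
        sum((signals - m)^2)
      }
      stats::optim(c(d, f, max(dstar, d + 1e-6)), obj, method = "L-BFGS-B",
                   lower = c(1e-6, 0, 1e-6), upper = c(0.01, 0.6, 0.5),
                   control = list(maxit = 500L,
                                  parscale = c(1e-3, 0.1, 1e-2)))$par
    }, error = function(e) NULL)
    if (!is.null(polished)) {
      d <- polished[1L]
      f <- polished[2L]
      dstar <- max(polished[3L], d)
    }
  } else {
    dstar <- fit_dstar(signals, bvalues, s0, d, f)
  }
  c(d = d, dstar = dstar, f = 100 * f)
}

# Bounded 1-D least squares for D* on [d, 0.5] with d and f fixed.
fit_dstar <- function(signals, bvalues, s0, d, f) {
  if (f <= 1e-8) return(d)    # mono-exponential: D* unidentifiable, pin to D
  sse <- function(ds) {
    m <- s0 * (f * exp(-bvalues * ds) + (1 - f) * exp(-bvalues * d))
    sum((signals - m)^2)
  }
  opt <- stats::optimize(sse, interval = c(d, 0.5), tol = 1e-9)
  max(opt$minimum, d)
}

#' Voxel-wise diffusion maps (ADC + IVIM)
#'
#' Fits the mono-exponential ADC and the segmented IVIM model at every
#' masked voxel. Invalid voxels (non-positive signals) are excluded and
#' counted.
#'
#' @param series a [dwi_series()].
#' @param mask logical 3D array on the same grid.
#' @inheritParams fit_ivim
#' @return An object of class `diffusion_maps`: 3D arrays `adc`, `d`,
#'   `dstar` (mm^2/s) and `f` (percent), `NA` outside valid masked voxels,
#'   plus `mask`, `valid`, `n_invalid` and `invalid_causes`.
#' @export
diffusion_maps <- function(series, mask, b_threshold = 200, refit = TRUE) {
  stop_if(!inherits(series, "dwi_series"), "`series` must be a dwi_series")
  stop_if(!identical(dim(series$volumes[[1L]]), dim(mask)),
          "mask and series are on different grids")
  stop_if(!any(mask), "empty mask")
  b <- series$bvalues
  sm <- sapply(series$volumes, function(v) v[which(mask)])
  sm <- matrix(sm, ncol = length(b))

  nonpos <- apply(sm, 1L, function(s) any(!is.finite(s)) || any(s <= 0))
  adc <- rep(NA_real_, nrow(sm))
  ok <- !nonpos
  if (any(ok)) {
    # closed-form OLS slope, vectorised over voxels
    y <- log(sm[ok, , drop = FALSE])
    bc <- b - mean(b)
    adc[ok] <- -as.vector(y %*% bc) / sum(bc^2)
  }

  iv <- matrix(NA_real_, nrow(sm), 3L,
               dimnames = list(NULL, c("d", "dstar", "f")))
  for (i in which(ok)) {
    iv[i, ] <- fit_ivim(sm[i, ], b, b_threshold = b_threshold, refit = refit)
  }
  bad_fit <- ok & !is.finite(iv[, "d"])
  valid_v <- ok & is.finite(iv[, "d"])

  causes <- c(nonpositive_signal = sum(nonpos), fit_failure = sum(bad_fit))
  stop_if(!any(valid_v),
          paste0("all masked voxels invalid: ",
                 paste(names(causes), causes, sep = "=", collapse = ", ")))

  put <- function(v) {
    a <- array(NA_real_, dim(mask))
    a[which(mask)] <- v
    a
  }
  valid <- array(FALSE, dim(mask))
  valid[which(mask)] <- valid_v
  structure(list(adc = put(adc),
                 d = put(iv[, "d"]), dstar = put(iv[, "dstar"]),
                 f = put(iv[, "f"]),
                 mask = mask, valid = valid,
                 n_invalid = sum(!valid_v), invalid_causes = causes),
            class = "diffusion_maps")
}

#' @export
print.diffusion_maps <- function(x, ...) {
  cat(sprintf("<diffusion_maps> %d masked voxels (%d invalid)\n",
              sum(x$mask), x$n_invalid))
  invisible(x)
}
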