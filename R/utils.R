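# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' @noRd
is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

# Truncated normal draws by inverse-CDF; deterministic under set.seed().
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# The 13 unique 3D direction offsets at Chebyshev distance 1 (one of each
# antipodal pair, first non-zero component positive).
texture_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  keep <- apply(d, 1L, function(v) {
    nz <- v[v != 0]
    nz[1L] > 0
  })
  unname(d[keep, , drop = FALSE])
}

# All 26 neighbourhood offsets (3D, Chebyshev distance 1).
neighbour_offsets <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(d[rowSums(abs(d)) > 0, , drop = FALSE])
}

# Shift a 3D array by an integer offset, padding with NA.
shift_array <- function(a, offset) {
  d <- dim(a)
  out <- array(NA, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- offset[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) {
      dst[[k]] <- (1 + o):d[k]
      src[[k]] <- 1:(d[k] - o)
    } else {
      dst[[k]] <- 1:(d[k] + o)
      src[[k]] <- (1 - o):d[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Gaussian smoothing of a 3D array (reflection at edges via
# kernel renormalisation). sigma in voxels; sigma <= 0 returns the input.
smooth_gaussian3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {
    # m: matrix, smooth along rows (dim 1) for every column
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (j in seq_along(k)) {
      o <- j - r - 1L
      idx <- (1:n) + o
      ok <- idx >= 1L & idx <= n
      out[ok, ] <- out[ok, ] + k[j] * m[idx[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + k[j]
    }
    out / wsum
  }
  d <- dim(a)
  # axis 1
  a <- array(smooth1(matrix(a, d[1])), d)
  # axis 2
  a <- aperm(array(smooth1(matrix(aperm(a, c(2, 1, 3)), d[2])), d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  a <- aperm(array(smooth1(matrix(aperm(a, c(3, 1, 2)), d[3])), d[c(3, 1, 2)]), c(2, 3, 1))
  a
}

# Digital sphere mask centred on the grid.
sphere_mask <- function(dim3, radius) {
  ctr <- (dim3 + 1) / 2
  x <- slice.index(array(0, dim3), 1L) - ctr[1]
  y <- slice.index(array(0, dim3), 2L) - ctr[2]
  z <- slice.index(array(0, dim3), 3L) - ctr[3]
  (x^2 + y^2 + z^2) <= radius^2
}
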