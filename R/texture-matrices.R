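#' Fixed-bin-number discretisation of a map inside a mask
#'
#' Assigns every masked voxel an integer gray level in `1..ng` using
#' equal-width bins between the masked minimum and maximum (the maximum
#' maps to level `ng`). A constant map yields a single level. Fixed bin
#' number makes the resulting texture features invariant under affine
#' rescaling of the input map.
#'
#' @param map numeric 3D array.
#' @param mask logical 3D array on the same grid; only voxels where `mask`
#'   is `TRUE` and the map is finite are discretised.
#' @param ng number of gray levels (>= 2).
#' @return An object of class `discretised_roi`: list with `levels`
#'   (integer 3D array, `NA` outside the valid mask), `ng` and `bin_edges`.
#' @export
discretise <- function(map, mask, ng = 32L) {
  stop_if(!identical(dim(map), dim(mask)), "map and mask grids differ")
  stop_if(ng < 2L, "ng must be >= 2")
  valid <- mask & is.finite(map)
  stop_if(!any(valid), "no valid masked voxel")
  v <- map[valid]
  lo <- min(v); hi <- max(v)
  lev <- if (hi > lo) {
    pmin(ng, floor(ng * (v - lo) / (hi - lo)) + 1L)
  } else rep(1L, length(v))
  L <- array(NA_integer_, dim(map))
  L[which(valid)] <- as.integer(lev)
  structure(list(levels = L, ng = as.integer(ng),
                 bin_edges = seq(lo, hi, length.out = ng + 1L)),
            class = "discretised_roi")
}

#' Gray-level co-occurrence matrix (merged over directions)
#'
#' Counts level pairs at Chebyshev distance 1 for the 13 unique 3D
#' directions, symmetrises (each pair counted in both orders), pools the
#' counts over directions and normalises to probabilities. Only pairs with
#' both voxels inside the (valid) mask contribute.
#'
#' @param roi a [discretise()]d ROI.
#' @param directions integer matrix of direction offsets (rows), defaults
#'   to the 13 unique 3D directions at distance 1.
#' @param symmetric logical; count each pair in both orders (default).
#' @return `ng x ng` matrix of probabilities summing to 1.
#' @export
build_glcm <- function(roi, directions = texture_directions(),
                       symmetric = TRUE) {
  stop_if(!inherits(roi, "discretised_roi"), "`roi` must be a discretised_roi")
  L <- roi$levels
  ng <- roi$ng
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(directions))) {
    Ls <- shift_array(L, directions[r, ])
    both <- !is.na(L) & !is.na(Ls)
    if (!any(both)) next
    i <- L[both]; j <- Ls[both]
    counts <- counts + matrix(tabulate((i - 1L) * ng + j, nbins = ng * ng),
                              ng, ng, byrow = TRUE)
  }
  stop_if(sum(counts) == 0, "mask too small for any voxel pair")
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

#' Gray-level run-length matrix (merged over directions)
#'
#' Maximal runs of identical gray level along each of the 13 unique 3D
#' directions, broken at mask boundaries, pooled over directions.
#'
#' @inheritParams build_glcm
#' @return `ng x maxRunLength` count matrix; attribute `nv` holds the
#'   number of masked voxels times the number of directions (each voxel
#'   belongs to exactly one run per direction).
#' @export
build_glrlm <- function(roi, directions = texture_directions()) {
  stop_if(!inherits(roi, "discretised_roi"), "`roi` must be a discretised_roi")
  L <- roi$levels
  ng <- roi$ng
  w <- which(!is.na(L))
  idx <- which(!is.na(L), arr.ind = TRUE)
  lv <- L[w]
  n <- length(w)
  run_lv <- integer(0); run_len <- integer(0)
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    # integer line decomposition: t advances by s = |d|^2 between
    # consecutive voxels of a line; s*idx - t*d is constant on a line and
    # identifies it exactly
    s <- sum(d * d)
    t <- as.vector(idx %*% d)
    key <- s * idx - outer(t, d)
    ord <- order(key[, 1], key[, 2], key[, 3], t)
    k1 <- key[ord, 1]; k2 <- key[ord, 2]; k3 <- key[ord, 3]
    tt <- t[ord]; ll <- lv[ord]
    if (n == 1L) {
      newrun <- TRUE
    } else {
      newrun <- c(TRUE, diff(k1) != 0 | diff(k2) != 0 | diff(k3) != 0 |
                        diff(tt) != s | diff(ll) != 0)
    }
    rid <- cumsum(newrun)
    run_len <- c(run_len, tabulate(rid))
    run_lv <- c(run_lv, ll[newrun])
  }
  maxlen <- max(run_len)
  m <- matrix(0, ng, maxlen)
  for (k in seq_along(run_lv)) {
    m[run_lv[k], run_len[k]] <- m[run_lv[k], run_len[k]] + 1
  }
  attr(m, "nv") <- n * nrow(directions)
  m
}

#' Gray-level size-zone matrix
#'
#' Maximal 26-connected zones of identical gray level.
#'
#' @inheritParams build_glcm
#' @return `ng x maxZoneSize` count matrix; attribute `nv` holds the
#'   number of masked voxels (zones partition the mask).
#' @export
build_glszm <- function(roi) {
  stop_if(!inherits(roi, "discretised_roi"), "`roi` must be a discretised_roi")
  L <- roi$levels
  ng <- roi$ng
  w <- which(!is.na(L))
  lab <- array(NA_real_, dim(L))
  lab[w] <- as.numeric(w)
  offs <- neighbour_offsets()
  for (iter in seq_len(10000L)) {
    newlab <- lab
    for (r in seq_len(nrow(offs))) {
      Ls <- shift_array(L, offs[r, ])
      labs <- shift_array(lab, offs[r, ])
      same <- !is.na(L) & !is.na(Ls) & (L == Ls) & (labs < newlab)
      same[is.na(same)] <- FALSE
      newlab[same] <- labs[same]
    }
    if (identical(newlab, lab)) break
    lab <- newlab
  }
  zl <- lab[w]
  sizes <- as.vector(table(zl))
  zone_lab <- as.numeric(names(table(zl)))
  zone_lev <- L[w][match(zone_lab, zl)]
  maxsz <- max(sizes)
  m <- matrix(0, ng, maxsz)
  for (k in seq_along(sizes)) {
    m[zone_lev[k], sizes[k]] <- m[zone_lev[k], sizes[k]] + 1
  }
  attr(m, "nv") <- length(w)
  m
}

#' Neighbourhood gray-tone difference matrix
#'
#' For every masked voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its level and the mean level of those
#' neighbours; accumulated per gray level.
#'
#' @inheritParams build_glcm
#' @return list with `ni` (voxel count per level), `si` (summed absolute
#'   neighbourhood differences per level), `ng` and `nv` (total voxels
#'   contributing).
#' @export
build_ngtdm <- function(roi) {
  stop_if(!inherits(roi, "discretised_roi"), "`roi` must be a discretised_roi")
  L <- roi$levels
  ng <- roi$ng
  nb_sum <- array(0, dim(L))
  nb_cnt <- array(0L, dim(L))
  for (o in seq_len(26L)) {
    Ls <- shift_array(L, neighbour_offsets()[o, ])
    ok <- !is.na(Ls)
    nb_sum[ok] <- nb_sum[ok] + Ls[ok]
    nb_cnt[ok] <- nb_cnt[ok] + 1L
  }
  use <- !is.na(L) & nb_cnt > 0L
  lev <- L[use]
  abar <- nb_sum[use] / nb_cnt[use]
  ni <- tabulate(lev, nbins = ng)
  si <- numeric(ng)
  dd <- abs(lev - abar)
  agg <- rowsum(dd, group = lev)
  si[as.integer(rownames(agg))] <- agg[, 1L]
  list(ni = ni, si = si, ng = ng, nv = sum(ni))
}
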