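# IBSI-style feature evaluations on the texture matrices, plus first-order
# histogram statistics and the default 251-column feature panel.

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' GLCM cluster shade
#'
#' Third co-occurrence moment
#' `sum_ij (i + j - mu_i - mu_j)^3 p(i, j)`, measuring the skewness of the
#' co-occurrence distribution. The signed value is returned; reports in the
#' style of the published group-comparison table print its absolute value.
#'
#' @param glcm normalised co-occurrence probability matrix (entries sum
#'   to 1); unnormalised input is rejected.
#' @return signed cluster shade.
#' @export
glcm_cluster_shade <- function(glcm) {
  stop_if(abs(sum(glcm) - 1) > 1e-8, "GLCM must be normalised to sum to 1")
  ng <- nrow(glcm)
  i <- row(glcm); j <- col(glcm)
  mu_i <- sum(i * glcm); mu_j <- sum(j * glcm)
  sum((i + j - mu_i - mu_j)^3 * glcm)
}

#' Gray-level co-occurrence features
#'
#' The 25-feature GLCM family on a normalised co-occurrence matrix.
#' Degenerate (single-level) matrices take documented fallbacks:
#' correlation, the information measures and the difference/sum spreads
#' are 0.
#'
#' @inheritParams glcm_cluster_shade
#' @return named numeric vector.
#' @export
glcm_features <- function(glcm) {
  stop_if(abs(sum(glcm) - 1) > 1e-8, "GLCM must be normalised to sum to 1")
  ng <- nrow(glcm)
  p <- glcm
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)

  # diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  sa <- sum(k_sum * p_sum)

  hx <- -sum(xlog2(px)); hy <- -sum(xlog2(py))
  hxy <- -sum(xlog2(p))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * ifelse(pxy > 0, log2(pxy), 0))
  hxy2 <- -sum(xlog2(pxy))

  corr <- if (var_i > 0 && var_j > 0) {
    (sum(i * j * p) - mu_i * mu_j) / sqrt(var_i * var_j)
  } else 0
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  c(Autocorrelation = sum(i * j * p),
    JointAverage = mu_i,
    ClusterProminence = sum((i + j - mu_i - mu_j)^4 * p),
    ClusterShade = sum((i + j - mu_i - mu_j)^3 * p),
    ClusterTendency = sum((i + j - mu_i - mu_j)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(p_diff)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(p),
    SumAverage = sa,
    SumEntropy = -sum(xlog2(p_sum)),
    SumVariance = sum((k_sum - sa)^2 * p_sum),
    SumSquares = var_i,
    Dissimilarity = sum(abs(i - j) * p))
}

#' Gray-level run-length features
#'
#' The 16-feature GLRLM family on a (direction-merged) run-length count
#' matrix as built by [build_glrlm()].
#'
#' @param glrlm count matrix (levels x run length) with attribute `nv`.
#' @param nv number of voxel-direction incidences (defaults to the
#'   attribute).
#' @return named numeric vector.
#' @export
glrlm_features <- function(glrlm, nv = attr(glrlm, "nv")) {
  stop_if(is.null(nv), "nv (voxels x directions) is required")
  r <- glrlm
  nr <- sum(r)
  i <- row(r); l <- col(r)
  p <- r / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  c(ShortRunEmphasis = sum(r / l^2) / nr,
    LongRunEmphasis = sum(r * l^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(r)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(r)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(r)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(r)^2) / nr^2,
    RunPercentage = nr / nv,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunLengthVariance = sum((l - mu_l)^2 * p),
    RunEntropy = -sum(xlog2(p)),
    LowGrayLevelRunEmphasis = sum(r / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(r * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(r / (i^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(r * i^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(r * l^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(r * i^2 * l^2) / nr)
}

#' Gray-level size-zone features
#'
#' The 16-feature GLSZM family on a zone-size count matrix as built by
#' [build_glszm()].
#'
#' @param glszm count matrix (levels x zone size) with attribute `nv`.
#' @param nv number of masked voxels (defaults to the attribute).
#' @return named numeric vector.
#' @export
glszm_features <- function(glszm, nv = attr(glszm, "nv")) {
  stop_if(is.null(nv), "nv (masked voxel count) is required")
  z <- glszm
  nz <- sum(z)
  i <- row(z); s <- col(z)
  p <- z / nz
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  c(SmallAreaEmphasis = sum(z / s^2) / nz,
    LargeAreaEmphasis = sum(z * s^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(z)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(z)^2) / nz^2,
    SizeZoneNonUniformity = sum(colSums(z)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(colSums(z)^2) / nz^2,
    ZonePercentage = nz / nv,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    ZoneVariance = sum((s - mu_s)^2 * p),
    ZoneEntropy = -sum(xlog2(p)),
    LowGrayLevelZoneEmphasis = sum(z / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(z * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(z / (i^2 * s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(z * i^2 / s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(z * s^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(z * i^2 * s^2) / nz)
}

#' Neighbourhood gray-tone difference features
#'
#' Coarseness, contrast, busyness, complexity and strength from an NGTDM
#' as built by [build_ngtdm()]. Degenerate inputs take documented
#' fallbacks: a constant image has contrast/busyness/complexity/strength 0
#' and coarseness capped at 1e6.
#'
#' @param ngtdm list as returned by [build_ngtdm()].
#' @return named numeric vector.
#' @export
ngtdm_features <- function(ngtdm) {
  ni <- ngtdm$ni; si <- ngtdm$si; nv <- ngtdm$nv
  pres <- which(ni > 0)
  pi_ <- ni / nv
  ngp <- length(pres)
  denom_co <- sum(pi_ * si)
  coarseness <- if (denom_co > 0) 1 / denom_co else 1e6

  contrast <- if (ngp > 1) {
    g <- expand.grid(i = pres, j = pres)
    (sum(pi_[g$i] * pi_[g$j] * (g$i - g$j)^2) / (ngp * (ngp - 1))) *
      (sum(si) / nv)
  } else 0

  busy_den <- if (ngp > 1) {
    g <- expand.grid(i = pres, j = pres)
    sum(abs(g$i * pi_[g$i] - g$j * pi_[g$j]))
  } else 0
  busyness <- if (busy_den > 0) denom_co / busy_den else 0

  complexity <- if (ngp > 1) {
    g <- expand.grid(i = pres, j = pres)
    sum(abs(g$i - g$j) * (pi_[g$i] * si[g$i] + pi_[g$j] * si[g$j]) /
          (pi_[g$i] + pi_[g$j])) / nv
  } else 0

  strength <- if (sum(si) > 0 && ngp > 1) {
    g <- expand.grid(i = pres, j = pres)
    sum((pi_[g$i] + pi_[g$j]) * (g$i - g$j)^2) / sum(si)
  } else 0

  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' First-order (histogram) features
#'
#' 43 intensity and histogram statistics of the masked map values:
#' 21 percentiles (linear-interpolation convention), central moments
#' (population variance; skewness and raw kurtosis, 0 when degenerate),
#' robust spreads, energies and `ng`-bin histogram entropy, uniformity and
#' mode.
#'
#' @param map numeric 3D array (or plain numeric vector of values).
#' @param mask logical array; ignored when `map` is a vector.
#' @param ng histogram bin count for entropy/uniformity/mode.
#' @param spacing voxel spacing in mm (for total energy).
#' @return named numeric vector of length 43.
#' @export
first_order_features <- function(map, mask = NULL, ng = 32L,
                                 spacing = c(1, 1, 1)) {
  v <- if (is.null(mask)) as.numeric(map) else {
    stop_if(!any(mask), "empty mask")
    map[mask & is.finite(map)]
  }
  v <- v[is.finite(v)]
  stop_if(length(v) == 0L, "no valid values")
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  sdv <- sqrt(m2)
  qs <- stats::quantile(v, c(1, seq(5, 95, 5), 99) / 100, names = FALSE,
                        type = 7)
  names(qs) <- paste0("P", sprintf("%02d", c(1, seq(5, 95, 5), 99)))
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 else 0

  # ng-bin histogram over the value range (constant map: single bin)
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    lev <- pmin(ng, floor(ng * (v - lo) / (hi - lo)) + 1L)
  } else lev <- rep(1L, n)
  ph <- tabulate(lev, nbins = ng) / n
  mode_bin <- which.max(ph)
  mode_val <- if (hi > lo) lo + (mode_bin - 0.5) * (hi - lo) / ng else lo

  p10 <- qs[["P10"]]; p90 <- qs[["P90"]]
  mid <- v[v >= p10 & v <= p90]
  rmad <- if (length(mid)) mean(abs(mid - mean(mid))) else 0

  c(qs,
    Mean = m,
    Variance = m2,
    StdDev = sdv,
    CV = if (m != 0) sdv / abs(m) else 0,
    Skewness = skew,
    Kurtosis = kurt,
    Minimum = lo,
    Maximum = hi,
    Range = hi - lo,
    IQR = qs[["P75"]] - qs[["P25"]],
    MeanAbsDev = mean(abs(v - m)),
    RobustMeanAbsDev = rmad,
    MedianAbsDev = stats::median(abs(v - stats::median(v))),
    Energy = sum(v^2),
    TotalEnergy = sum(v^2) * prod(spacing),
    RMS = sqrt(mean(v^2)),
    Entropy = -sum(xlog2(ph)),
    Uniformity = sum(ph^2),
    Mode = mode_val,
    TrimmedMean05 = mean(v, trim = 0.05),
    TrimmedMean25 = mean(v, trim = 0.25),
    RobustRange = p90 - p10)
}

#' Default radiomics configuration
#'
#' The feature panel applied to the ADC and iAUC60 maps. Each map carries
#' 43 first-order, 25 GLCM, 16 GLRLM, 16 GLSZM and 5 NGTDM features (105);
#' the diffusion map additionally carries the absolute-value variant of the
#' GLCM cluster shade (the form in which the published group-comparison
#' table reports it), for 211 radiomic features. Together with the 40 ROI
#' statistics of the eight perfusion/diffusion biomarkers the per-patient
#' imaging feature count is 251.
#'
#' @param ng gray-level count for discretisation (default 32).
#' @return list with `ng` and the per-map feature `panels`.
#' @export
radiomics_config <- function(ng = 32L) {
  fo_names <- names(first_order_features(c(0, 0.5, 1)))
  base <- list(
    fo = fo_names,
    glcm = names(glcm_features(diag(2) / 2)),
    glrlm = names(glrlm_features(matrix(1, 2, 2), nv = 4)),
    glszm = names(glszm_features(matrix(1, 2, 2), nv = 4)),
    ngtdm = names(ngtdm_features(list(ni = c(2, 2), si = c(1, 1), nv = 4))))
  panels <- list(
    ADC = c(base, list(extra = "glcm_ClusterShadeAbs")),
    iAUC60 = base)
  list(ng = as.integer(ng), panels = panels)
}

# Compute every configured family for one map; returns the prefixed
# named vector.
radiomics_one_map <- function(map, mask, prefix, panel, ng, spacing) {
  valid <- mask & is.finite(map)
  stop_if(!any(valid), sprintf("map '%s' has no valid masked voxel", prefix))
  roi <- discretise(map, mask, ng)
  glcm <- build_glcm(roi)
  out <- c(
    stats::setNames(first_order_features(map, mask, ng = ng,
                                         spacing = spacing)[panel$fo],
                    paste0(prefix, "_fo_", panel$fo)),
    stats::setNames(glcm_features(glcm)[panel$glcm],
                    paste0(prefix, "_glcm_", panel$glcm)),
    stats::setNames(glrlm_features(build_glrlm(roi))[panel$glrlm],
                    paste0(prefix, "_glrlm_", panel$glrlm)),
    stats::setNames(glszm_features(build_glszm(roi))[panel$glszm],
                    paste0(prefix, "_glszm_", panel$glszm)),
    stats::setNames(ngtdm_features(build_ngtdm(roi))[panel$ngtdm],
                    paste0(prefix, "_ngtdm_", panel$ngtdm)))
  if (!is.null(panel$extra) && "glcm_ClusterShadeAbs" %in% panel$extra) {
    out <- c(out, stats::setNames(abs(glcm_cluster_shade(glcm)),
                                  paste0(prefix, "_glcm_ClusterShadeAbs")))
  }
  out
}

#' Radiomic feature extraction on the ADC and iAUC60 maps
#'
#' Applies the configured first-order and texture feature panel to the two
#' heterogeneity maps inside the tumour mask.
#'
#' @param maps named list with elements `adc` and `iauc60` (3D arrays on
#'   the mask grid; `NA` allowed outside the valid voxels).
#' @param mask logical 3D array.
#' @param config a [radiomics_config()].
#' @param spacing voxel spacing in mm.
#' @return named numeric vector of 211 features, names prefixed
#'   `ADC_` / `iAUC60_` and by family (`fo`, `glcm`, `glrlm`, `glszm`,
#'   `ngtdm`), e.g. `ADC_glcm_ClusterShade`.
#' @export
extract_radiomics <- function(maps, mask, config = radiomics_config(),
                              spacing = c(1, 1, 1)) {
  for (nm in c("adc", "iauc60")) {
    stop_if(is.null(maps[[nm]]), sprintf("missing map '%s'", nm))
    stop_if(!identical(dim(maps[[nm]]), dim(mask)),
            sprintf("map '%s' is not on the mask grid", nm))
  }
  c(radiomics_one_map(maps$adc, mask, "ADC", config$panels$ADC,
                      config$ng, spacing),
    radiomics_one_map(maps$iauc60, mask, "iAUC60", config$panels$iAUC60,
                      config$ng, spacing))
}
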