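# Independent brute-force oracles for the texture and first-order features.
# Everything here is written as explicit enumeration (voxel/pair/run/zone
# loops and naive formula sums), deliberately not sharing code with the
# package implementations.

# -- matrix oracles -----------------------------------------------------------

oracle_glcm <- function(levels, ng, directions, symmetric = TRUE) {
  d <- dim(levels)
  counts <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(directions))) {
      xx <- x + directions[r, 1]; yy <- y + directions[r, 2]
      zz <- z + directions[r, 3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
      b <- levels[xx, yy, zz]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      if (symmetric) counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

oracle_glrlm <- function(levels, ng, directions) {
  d <- dim(levels)
  runs <- list()
  inb <- function(x, y, z) x >= 1 && x <= d[1] && y >= 1 && y <= d[2] &&
    z >= 1 && z <= d[3]
  val <- function(x, y, z) if (inb(x, y, z)) levels[x, y, z] else NA
  for (r in seq_len(nrow(directions))) {
    dx <- directions[r, 1]; dy <- directions[r, 2]; dz <- directions[r, 3]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- levels[x, y, z]
      if (is.na(a)) next
      prev <- val(x - dx, y - dy, z - dz)
      if (!is.na(prev) && prev == a) next          # not a run start
      len <- 1
      while (TRUE) {
        nxt <- val(x + len * dx, y + len * dy, z + len * dz)
        if (is.na(nxt) || nxt != a) break
        len <- len + 1
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
  }
  runs <- do.call(rbind, runs)
  m <- matrix(0, ng, max(runs[, 2]))
  for (k in seq_len(nrow(runs))) {
    m[runs[k, 1], runs[k, 2]] <- m[runs[k, 1], runs[k, 2]] + 1
  }
  attr(m, "nv") <- sum(!is.na(levels)) * nrow(directions)
  m
}

oracle_glszm <- function(levels, ng) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(levels[x, y, z]) || seen[x, y, z]) next
    lev <- levels[x, y, z]
    # depth-first flood fill over 26-connected equal-level voxels
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1) || any(w > d)) next
        if (seen[w[1], w[2], w[3]]) next
        lw <- levels[w[1], w[2], w[3]]
        if (is.na(lw) || lw != lev) next
        seen[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1]] <- w
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  zones <- do.call(rbind, zones)
  m <- matrix(0, ng, max(zones[, 2]))
  for (k in seq_len(nrow(zones))) {
    m[zones[k, 1], zones[k, 2]] <- m[zones[k, 1], zones[k, 2]] + 1
  }
  attr(m, "nv") <- sum(!is.na(levels))
  m
}

oracle_ngtdm <- function(levels, ng) {
  d <- dim(levels)
  ni <- numeric(ng); si <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] || zz < 1 || zz > d[3]) next
      v <- levels[xx, yy, zz]
      if (!is.na(v)) nb <- c(nb, v)
    }
    if (length(nb) == 0) next
    ni[a] <- ni[a] + 1
    si[a] <- si[a] + abs(a - mean(nb))
  }
  list(ni = ni, si = si, ng = ng, nv = sum(ni))
}

# -- feature oracles (naive double-loop formula evaluations) ------------------

oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  mui <- 0; muj <- 0
  for (i in 1:ng) for (j in 1:ng) { mui <- mui + i * p[i, j]; muj <- muj + j * p[i, j] }
  vi <- 0; vj <- 0; auto <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0
  je <- 0; jent <- 0; idm <- 0; idmn <- 0; id <- 0; idn <- 0; iv <- 0
  dis <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    vi <- vi + (i - mui)^2 * v; vj <- vj + (j - muj)^2 * v
    auto <- auto + i * j * v
    cp <- cp + (i + j - mui - muj)^4 * v
    cs <- cs + (i + j - mui - muj)^3 * v
    ct <- ct + (i + j - mui - muj)^2 * v
    con <- con + (i - j)^2 * v
    je <- je + v^2
    if (v > 0) jent <- jent - v * log2(v)
    idm <- idm + v / (1 + (i - j)^2)
    idmn <- idmn + v / (1 + ((i - j) / ng)^2)
    id <- id + v / (1 + abs(i - j))
    idn <- idn + v / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + v / (i - j)^2
    dis <- dis + abs(i - j) * v
  }
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  da <- sum((0:(ng - 1)) * pd); sa <- sum((2:(2 * ng)) * ps)
  dent <- -sum(ifelse(pd > 0, pd * log2(pd), 0))
  dvar <- sum(((0:(ng - 1)) - da)^2 * pd)
  sent <- -sum(ifelse(ps > 0, ps * log2(ps), 0))
  svar <- sum(((2:(2 * ng)) - sa)^2 * ps)
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hy <- -sum(ifelse(py > 0, py * log2(py), 0))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy1 <- hxy1 - p[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  corr <- if (vi > 0 && vj > 0) (auto - mui * muj) / sqrt(vi * vj) else 0
  c(Autocorrelation = auto, JointAverage = mui, ClusterProminence = cp,
    ClusterShade = cs, ClusterTendency = ct, Contrast = con,
    Correlation = corr, DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, JointEnergy = je, JointEntropy = jent,
    Imc1 = if (max(hx, hy) > 0) (jent - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - jent)))),
    Idm = idm, Idmn = idmn, Id = id, Idn = idn, InverseVariance = iv,
    MaximumProbability = max(p), SumAverage = sa, SumEntropy = sent,
    SumVariance = svar, SumSquares = vi, Dissimilarity = dis)
}

oracle_rl_features <- function(m, nv, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  ng <- nrow(m); nl <- ncol(m)
  nr <- sum(m)
  sre <- 0; lre <- 0; lgl <- 0; hgl <- 0; srl <- 0; srh <- 0; lrl <- 0
  lrh <- 0; ent <- 0
  mui <- 0; mul <- 0
  for (i in 1:ng) for (l in 1:nl) {
    v <- m[i, l]; pv <- v / nr
    sre <- sre + v / l^2; lre <- lre + v * l^2
    lgl <- lgl + v / i^2; hgl <- hgl + v * i^2
    srl <- srl + v / (i^2 * l^2); srh <- srh + v * i^2 / l^2
    lrl <- lrl + v * l^2 / i^2; lrh <- lrh + v * i^2 * l^2
    if (pv > 0) ent <- ent - pv * log2(pv)
    mui <- mui + i * pv; mul <- mul + l * pv
  }
  glv <- 0; rlv <- 0
  for (i in 1:ng) for (l in 1:nl) {
    pv <- m[i, l] / nr
    glv <- glv + (i - mui)^2 * pv
    rlv <- rlv + (l - mul)^2 * pv
  }
  gln <- sum(rowSums(m)^2); rln <- sum(colSums(m)^2)
  out <- c(sre / nr, lre / nr, gln / nr, gln / nr^2, rln / nr, rln / nr^2,
           nr / nv, glv, rlv, ent, lgl / nr, hgl / nr, srl / nr, srh / nr,
           lrl / nr, lrh / nr)
  names(out) <- if (kind == "run") {
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunLengthVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  } else {
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  }
  out
}

oracle_ngtdm_features <- function(ngt) {
  ni <- ngt$ni; si <- ngt$si; nv <- ngt$nv; ng <- ngt$ng
  pi_ <- ni / nv
  pres <- which(ni > 0)
  ngp <- length(pres)
  den <- 0
  for (i in pres) den <- den + pi_[i] * si[i]
  coarse <- if (den > 0) 1 / den else 1e6
  con <- 0; busy_den <- 0; comp <- 0; str <- 0
  if (ngp > 1) {
    for (i in pres) for (j in pres) {
      con <- con + pi_[i] * pi_[j] * (i - j)^2
      busy_den <- busy_den + abs(i * pi_[i] - j * pi_[j])
      comp <- comp + abs(i - j) * (pi_[i] * si[i] + pi_[j] * si[j]) /
        (pi_[i] + pi_[j])
      str <- str + (pi_[i] + pi_[j]) * (i - j)^2
    }
    con <- con / (ngp * (ngp - 1)) * sum(si) / nv
    comp <- comp / nv
  }
  c(Coarseness = coarse,
    Contrast = if (ngp > 1) con else 0,
    Busyness = if (busy_den > 0) den / busy_den else 0,
    Complexity = if (ngp > 1) comp else 0,
    Strength = if (sum(si) > 0 && ngp > 1) str / sum(si) else 0)
}

# first-order oracle: direct formulas on the sorted values
oracle_first_order <- function(v, ng = 32, spacing = c(1, 1, 1)) {
  v <- sort(v)
  n <- length(v)
  pct <- function(q) {                     # linear interpolation, R type 7
    h <- (n - 1) * q + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  qs <- sapply(c(1, seq(5, 95, 5), 99) / 100, pct)
  names(qs) <- paste0("P", sprintf("%02d", c(1, seq(5, 95, 5), 99)))
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  hist_lev <- if (max(v) > min(v)) {
    pmin(ng, floor(ng * (v - min(v)) / (max(v) - min(v))) + 1)
  } else rep(1, n)
  ph <- as.numeric(table(factor(hist_lev, levels = 1:ng))) / n
  mode_bin <- which.max(ph)
  mid <- v[v >= qs[["P10"]] & v <= qs[["P90"]]]
  c(qs,
    Mean = m, Variance = m2, StdDev = sqrt(m2),
    CV = if (m != 0) sqrt(m2) / abs(m) else 0,
    Skewness = if (m2 > 0) (sum((v - m)^3) / n) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) (sum((v - m)^4) / n) / m2^2 else 0,
    Minimum = min(v), Maximum = max(v), Range = max(v) - min(v),
    IQR = qs[["P75"]] - qs[["P25"]],
    MeanAbsDev = sum(abs(v - m)) / n,
    RobustMeanAbsDev = if (length(mid)) sum(abs(mid - mean(mid))) / length(mid) else 0,
    MedianAbsDev = pct_med_abs(v),
    Energy = sum(v^2), TotalEnergy = sum(v^2) * prod(spacing),
    RMS = sqrt(sum(v^2) / n),
    Entropy = -sum(ifelse(ph > 0, ph * log2(ph), 0)),
    Uniformity = sum(ph^2),
    Mode = if (max(v) > min(v)) {
      min(v) + (mode_bin - 0.5) * (max(v) - min(v)) / ng
    } else min(v),
    TrimmedMean05 = mean(v, trim = 0.05),
    TrimmedMean25 = mean(v, trim = 0.25),
    RobustRange = qs[["P90"]] - qs[["P10"]])
}

pct_med_abs <- function(v) {
  med <- stats::median(v)
  stats::median(abs(v - med))
}

# random small discretised test image (levels with NA outside a random mask)
random_levels <- function(dims, ng, seed, mask_prob = 0.8) {
  set.seed(seed)
  L <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  keep <- array(stats::runif(prod(dims)) < mask_prob, dims)
  if (!any(keep)) keep[1] <- TRUE
  L[!keep] <- NA_integer_
  L
}

# wrap a plain level array as the package's discretised ROI
as_roi <- function(levels, ng) {
  structure(list(levels = levels, ng = as.integer(ng),
                 bin_edges = seq(0, 1, length.out = ng + 1)),
            class = "discretised_roi")
}

# numeric integration of the gamma-variate truth curve on a fine grid
oracle_iauc <- function(peak, ttp, onset, alpha, window = 60, dt = 0.01) {
  tt <- seq(0, window, by = dt)
  cc <- mpMRIpcr::gamma_variate(tt, peak, ttp, onset, alpha)
  sum((cc[-1] + cc[-length(cc)]) / 2 * dt)
}
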