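# IBSI texture matrices and features.

test_that("fixed-bin-number discretisation maps range endpoints correctly", {
  m <- array(seq(0, 1, length.out = 27), c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  roi <- discretise(m, mask, ng = 32)
  expect_equal(roi$levels[which(m == 0)], 1L)
  expect_equal(roi$levels[which(m == 1)], 32L)
  # constant map: single level, GLCM concentrates to one entry
  roic <- discretise(array(5, c(3, 3, 3)), mask, ng = 32)
  expect_true(all(roic$levels == 1L))
  g <- build_glcm(roic)
  expect_equal(sum(g > 0), 1)
  expect_equal(g[1, 1], 1)
  # bin counts invariant under affine rescaling
  roi2 <- discretise(3 * m - 10, mask, ng = 32)
  expect_equal(tabulate(roi$levels, 32), tabulate(roi2$levels, 32))
})

test_that("GLCM of the 1x4 strip matches pair enumeration", {
  L <- array(NA_integer_, c(4, 1, 1))
  L[, 1, 1] <- c(1L, 1L, 1L, 2L)
  roi <- as_roi(L, 2)
  g <- build_glcm(roi, directions = matrix(c(1, 0, 0), 1))
  expect_equal(g[1, 1], 4 / 6)
  expect_equal(g[1, 2], 1 / 6)
  expect_equal(g[2, 1], 1 / 6)
  expect_equal(g[2, 2], 0)
})

test_that("cluster shade matches the hand-evaluated cubed moment", {
  g <- matrix(c(2 / 3, 1 / 6, 1 / 6, 0), 2, 2)
  expect_equal(glcm_cluster_shade(g), 6 / 81, tolerance = 1e-12)
  expect_error(glcm_cluster_shade(2 * g), "normalised")
  # constant image -> 0
  gc <- matrix(0, 3, 3); gc[1, 1] <- 1
  expect_equal(glcm_cluster_shade(gc), 0)
  # symmetric GLCM: transpose leaves the shade unchanged
  set.seed(3)
  a <- matrix(runif(16), 4); a <- a + t(a); a <- a / sum(a)
  expect_equal(glcm_cluster_shade(a), glcm_cluster_shade(t(a)))
})

test_that("cluster shade is odd under gray-level reflection", {
  for (seed in 1:8) {
    L <- random_levels(c(4, 4, 3), ng = 5, seed = seed)
    roi <- as_roi(L, 5)
    refl <- as_roi(array(ifelse(is.na(L), NA_integer_, 6L - L), dim(L)), 5)
    expect_equal(glcm_cluster_shade(build_glcm(roi)),
                 -glcm_cluster_shade(build_glcm(refl)),
                 tolerance = 1e-12)
  }
})

test_that("GLCM features are invariant under affine intensity rescaling", {
  set.seed(41)
  m <- array(rnorm(64), c(4, 4, 4))
  mask <- array(runif(64) < 0.85, c(4, 4, 4))
  f1 <- glcm_features(build_glcm(discretise(m, mask, 8)))
  f2 <- glcm_features(build_glcm(discretise(-2.5 * m + 7, mask, 8)))
  # reflection flips the level order; even-moment features are preserved
  expect_equal(f1[["Contrast"]], f2[["Contrast"]], tolerance = 1e-12)
  f3 <- glcm_features(build_glcm(discretise(2.5 * m + 7, mask, 8)))
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("run-length enumeration matches the strip example", {
  L <- array(NA_integer_, c(4, 1, 1))
  L[, 1, 1] <- c(1L, 1L, 2L, 2L)
  m <- build_glrlm(as_roi(L, 2), directions = matrix(c(1, 0, 0), 1))
  expect_equal(m[1, 2], 1)          # one run of level 1, length 2
  expect_equal(m[2, 2], 1)
  expect_equal(sum(m), 2)
  feats <- glrlm_features(m)
  expect_equal(feats[["RunPercentage"]], 2 / 4)
})

test_that("run and zone totals conserve the voxel count", {
  for (seed in 1:5) {
    L <- random_levels(c(5, 4, 3), ng = 4, seed = seed)
    nvox <- sum(!is.na(L))
    r <- build_glrlm(as_roi(L, 4))
    lenmat <- matrix(rep(seq_len(ncol(r)), each = nrow(r)), nrow(r))
    expect_equal(sum(r * lenmat), nvox * 13)     # every voxel in one run/direction
    z <- build_glszm(as_roi(L, 4))
    szmat <- matrix(rep(seq_len(ncol(z)), each = nrow(z)), nrow(z))
    expect_equal(sum(z * szmat), nvox)           # zones partition the mask
  }
})

test_that("NGTDM coarseness separates checkerboard from constant", {
  chk <- array(NA_integer_, c(4, 4, 1))
  chk[, , 1] <- (outer(1:4, 1:4, `+`) %% 2) + 1L
  fc <- ngtdm_features(build_ngtdm(as_roi(chk, 2)))
  const <- as_roi(array(1L, c(4, 4, 1)), 2)
  f0 <- ngtdm_features(build_ngtdm(const))
  expect_equal(f0[["Coarseness"]], 1e6)          # capped degenerate maximum
  expect_lt(fc[["Coarseness"]], f0[["Coarseness"]])
  expect_equal(f0[["Contrast"]], 0)
  expect_equal(f0[["Busyness"]], 0)
})

test_that("every texture family matches its exhaustive enumeration oracle", {
  dims_list <- list(c(4, 4, 1), c(3, 3, 3))
  dirs <- mpMRIpcr:::texture_directions()
  for (seed in 1:6) {
    for (dims in dims_list) {
      ng <- if (seed %% 2) 4L else 6L
      L <- random_levels(dims, ng, seed = seed * 97L)
      roi <- as_roi(L, ng)
      expect_equal(build_glcm(roi), oracle_glcm(L, ng, dirs), tolerance = 1e-12)
      got_r <- build_glrlm(roi); want_r <- oracle_glrlm(L, ng, dirs)
      expect_equal(unname(got_r[, seq_len(ncol(want_r))]), unname(want_r),
                   ignore_attr = TRUE)
      got_z <- build_glszm(roi); want_z <- oracle_glszm(L, ng)
      expect_equal(unname(got_z[, seq_len(ncol(want_z))]), unname(want_z),
                   ignore_attr = TRUE)
      expect_equal(build_ngtdm(roi)[c("ni", "si")],
                   oracle_ngtdm(L, ng)[c("ni", "si")], tolerance = 1e-12)
    }
  }
})

test_that("first-order features match direct formula evaluation", {
  expect_equal(first_order_features(c(1, 2, 3, 4))[["Mean"]], 2.5)
  expect_equal(first_order_features(c(1, 2, 3, 4))[["Range"]], 3)
  cf <- first_order_features(rep(3.3, 10))
  expect_equal(cf[["Variance"]], 0)
  expect_equal(cf[["Entropy"]], 0)
  expect_equal(cf[["Uniformity"]], 1)
  set.seed(8)
  for (k in 1:5) {
    v <- rnorm(50, sd = 2)
    expect_equal(first_order_features(v), oracle_first_order(v),
                 tolerance = 1e-12)
  }
  # large-sample skewness of a Gaussian draw is near zero
  set.seed(99)
  expect_lt(abs(first_order_features(rnorm(1e5))[["Skewness"]]), 0.05)
})

test_that("the default radiomics panel yields the published feature width", {
  cfg <- radiomics_config()
  n_rad <- sum(lengths(cfg$panels$ADC)) + sum(lengths(cfg$panels$iAUC60))
  expect_equal(n_rad, 211)
  expect_equal(n_rad + 8 * 5, 251)
  set.seed(12)
  m1 <- array(rnorm(5^3, 1e-3, 1e-4), c(5, 5, 5))
  m2 <- array(abs(rnorm(5^3, 30, 10)), c(5, 5, 5))
  mask <- sphere <- array(TRUE, c(5, 5, 5))
  rad <- extract_radiomics(list(adc = m1, iauc60 = m2), mask)
  expect_equal(length(rad), 211)
  expect_true("ADC_glcm_ClusterShade" %in% names(rad))
  expect_true(all(is.finite(rad)))
  expect_equal(rad[["ADC_glcm_ClusterShadeAbs"]],
               abs(rad[["ADC_glcm_ClusterShade"]]))
  # determinism: identical input, identical features
  expect_identical(rad, extract_radiomics(list(adc = m1, iauc60 = m2), mask))
  expect_error(extract_radiomics(list(adc = m1), mask), "iauc60")
})
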