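# Semi-quantitative DCE perfusion biomarkers.

test_that("signal-to-concentration conversion is relative enhancement", {
  arr <- array(100, c(1, 1, 1, 4))
  times <- c(-40, 0, 40, 80)
  s <- dce_series(arr, times, injection_time = 0)
  conc <- signal_to_concentration(s)
  expect_equal(as.numeric(conc$values), rep(0, 4))          # no enhancement
  arr[1, 1, 1, 3] <- 150
  conc <- signal_to_concentration(dce_series(arr, times, 0))
  expect_equal(conc$values[1, 1, 1, 3], 0.5)                # (150-100)/100
  conc2 <- signal_to_concentration(dce_series(arr, times, 0),
                                   relaxivity_scale = 2)
  expect_equal(conc2$values[1, 1, 1, 3], 1.0)               # linear in scale
  # non-positive baseline flags the voxel invalid
  arr0 <- arr; arr0[1, 1, 1, 1:2] <- 0
  expect_false(signal_to_concentration(dce_series(arr0, times, 0))$valid[1, 1, 1])
})

test_that("peak and TTP follow the first-attainment maximum convention", {
  curve <- c(0, 0.5, 1.2, 0.9, 0.8, 0.7)
  times <- c(0, 40, 80, 120, 160, 200)
  expect_equal(compute_peak(curve, times, 0), 1.2)
  expect_equal(compute_ttp(curve, times, 0), 80)
  expect_equal(compute_peak(rep(0, 6), times, 0), 0)
  # monotone increasing -> last sample; plateau -> first attainment
  expect_equal(compute_ttp(seq(0, 1, length.out = 6), times, 0), 200)
  expect_equal(compute_ttp(c(0, 0.4, 1, 1, 1, 1), times, 0), 80)
  # two equal maxima: same peak value wherever they sit
  expect_equal(compute_peak(c(0, 1, 0.2, 1, 0, 0), times, 0), 1)
  expect_error(compute_peak(curve, times, injection_time = 500), "empty")
})

test_that("iAUC60 integrates the first post-injection minute", {
  times <- c(-40, 0, 40, 80, 120)
  expect_equal(compute_iauc60(c(0, 1, 1, 1, 1), times, 0), 60)   # rectangle
  ramp <- pmax(times, 0) / 60
  expect_equal(compute_iauc60(ramp, times, 0), 30)               # triangle
  # additivity and linear scaling
  c1 <- c(0, 0.2, 0.9, 1.2, 0.3); c2 <- c(0, 0.5, 0.1, 0.4, 0.8)
  expect_equal(compute_iauc60(c1 + c2, times, 0),
               compute_iauc60(c1, times, 0) + compute_iauc60(c2, times, 0))
  expect_equal(compute_iauc60(3 * c1, times, 0),
               3 * compute_iauc60(c1, times, 0))
  expect_error(compute_iauc60(c1[1:3], times[1:3], 0), "60")
  # endpoint interpolation: window end between samples
  times2 <- c(-40, 0, 45, 90)
  vals <- c(0, 0, 0.9, 1.8)                        # linear ramp 0.02/s from 0
  expect_equal(compute_iauc60(vals, times2, 0), 0.5 * 60 * 1.2)
})

test_that("iAUC60 of sampled gamma-variate curves tracks fine-grid oracle integration", {
  # adequate sampling: 5 s; the 40 s protocol comb is checked via TTP
  for (ttp in c(60, 120, 200)) {
    tt <- seq(-20, 400, by = 5)
    cc <- gamma_variate(tt, peak = 1, ttp = ttp, onset = 0, alpha = 3)
    got <- compute_iauc60(cc, tt, 0)
    want <- oracle_iauc(1, ttp, 0, 3)
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("initial slope takes the steepest pre-peak rise after onset", {
  times <- c(0, 40, 80, 120)
  expect_equal(compute_initial_slope(c(0, 0.4, 1.2, 0.9), times, 0),
               (1.2 - 0.4) / 40)
  expect_equal(compute_initial_slope(rep(0, 4), times, 0), 0)
  # linear ramp to the peak: slope equals the ramp rate
  expect_equal(compute_initial_slope(c(0, 0.5, 1.0, 1.5), times, 0), 0.5 / 40)
})

test_that("TTP is invariant to positive curve rescaling, peak bounds hold", {
  set.seed(5)
  times <- seq(-40, 280, by = 40)
  for (k in 1:20) {
    curve <- c(0, abs(rnorm(length(times) - 1)))
    expect_equal(compute_ttp(curve, times, 0), compute_ttp(5 * curve, times, 0))
    pk <- compute_peak(curve, times, 0)
    expect_true(all(pk >= curve[times >= 0]))
    expect_lte(compute_iauc60(curve, times, 0), 60 * pk + 1e-12)
  }
})

test_that("voxel-wise perfusion maps recover noiseless truth on the mask", {
  spec <- noiseless_spec(seed = 5)
  p <- generate_patient(spec, "non_pcr", seed = 21)
  pm <- perfusion_maps(p$dce, p$mask)
  expect_s3_class(pm, "perfusion_maps")
  # domain preservation: defined exactly on the mask
  expect_identical(is.na(pm$ttp), !p$mask)
  # truth recovery at sample resolution
  expect_equal(pm$ttp[p$mask], p$truth$ttp[p$mask], tolerance = 1e-12)
  expect_equal(pm$peak[p$mask], p$truth$peak[p$mask], tolerance = 1e-6)
  expect_error(perfusion_maps(p$dce, array(FALSE, dim(p$mask))), "empty")
  # single-voxel mask gives scalar-per-biomarker maps
  m1 <- array(FALSE, dim(p$mask))
  m1[8, 8, 8] <- TRUE
  pm1 <- perfusion_maps(p$dce, m1)
  expect_equal(sum(!is.na(pm1$iauc60)), 1)
})
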