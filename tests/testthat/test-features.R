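# ROI statistics, table assembly, two-step selection, group statistics.

test_that("ROI statistics use linear-interpolation percentiles", {
  m <- array(NA_real_, c(4, 1, 1)); m[, 1, 1] <- c(1, 2, 3, 4)
  mask <- array(TRUE, c(4, 1, 1))
  s <- roi_statistics(m, mask)
  expect_equal(s[["p25"]], 1.75)
  expect_equal(s[["median"]], 2.5)
  expect_equal(s[["p75"]], 3.25)
  expect_equal(s[["mean"]], 2.5)
  # constant map and single voxel
  sc <- roi_statistics(array(7, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
  expect_equal(unname(sc), c(7, 7, 0, 7, 7))
  m1 <- array(FALSE, c(4, 1, 1)); m1[2, 1, 1] <- TRUE
  s1 <- roi_statistics(m, m1)
  expect_equal(unname(s1), c(2, 2, 0, 2, 2))
  # percentile agrees with a sort-and-interpolate oracle on random vectors
  set.seed(31)
  for (k in 1:10) {
    v <- rnorm(15 + k)
    mm <- array(v, c(length(v), 1, 1))
    s <- roi_statistics(mm, array(TRUE, dim(mm)))
    h <- (length(v) - 1) * 0.25 + 1
    vv <- sort(v)
    expect_equal(s[["p25"]], vv[floor(h)] + (h - floor(h)) *
                   (vv[floor(h) + 1] - vv[floor(h)]))
  }
})

test_that("feature table assembly yields the three configuration views", {
  n <- 10
  imaging <- matrix(rnorm(n * 6), n, 6,
                    dimnames = list(sprintf("P%02d", 1:n), paste0("img", 1:6)))
  clinical <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
                     dimnames = list(NULL, c("age_over_40", "premenopausal",
                                             "stage_iii", "grade_iii")))
  labels <- rep(c(1, 0), each = 5)
  ft <- assemble_feature_table(imaging, clinical, labels)
  expect_equal(ncol(feature_view(ft, "imaging")), 6)
  expect_equal(ncol(feature_view(ft, "clinical")), 4)
  expect_equal(ncol(feature_view(ft, "combined")), 10)
  expect_error(assemble_feature_table(imaging[1:9, ], clinical, labels),
               "missing")
  rownames(imaging)[2] <- "P01"
  expect_error(assemble_feature_table(imaging, clinical, labels), "duplicate")
})

test_that("variance filter removes at and below the threshold, inclusively", {
  x <- cbind(constant = rep(1, 30),
             at_thresh = sqrt(0.1) * scale(rnorm(30))[, 1] * sqrt(29 / 30),
             keep = rnorm(30, sd = 5))
  # force the variance of column 2 to exactly 0.1
  x[, 2] <- x[, 2] / sd(x[, 2]) * sqrt(0.1)
  vf <- variance_filter(x, 0.1, scaling = "raw")
  expect_setequal(vf$removed, c("constant", "at_thresh"))
  expect_equal(vf$retained, "keep")
  expect_error(variance_filter(x[, 1, drop = FALSE], 0.1), "every column")
})

test_that("correlation filter keeps the higher-variance member of a pair", {
  set.seed(2)
  xx <- rnorm(40)
  x <- cbind(X = xx, Y = 2 * xx, Z = rnorm(40))
  cf <- correlation_filter(x, 0.8)
  expect_setequal(cf$retained, c("Y", "Z"))      # var(Y) = 4 var(X)
  expect_equal(cf$log$name, "X")
  expect_equal(cf$log$partner, "Y")
  # three mutual duplicates leave exactly the max-variance survivor
  x3 <- cbind(a = xx, b = 3 * xx, c = 2 * xx)
  expect_equal(correlation_filter(x3, 0.8)$retained, "b")
  # orthogonal columns untouched
  xo <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, letters[1:5]))
  expect_equal(length(correlation_filter(xo, 0.8)$retained), 5)
})

test_that("two-step selection retains exactly the informative columns", {
  x <- selection_fixture()
  # fixture sanity: informative columns are mutually below the threshold
  ci <- stats::cor(x[, 1:10]); diag(ci) <- 0
  expect_lt(max(abs(ci)), 0.8)
  sel <- select_features(x)
  expect_setequal(sel$retained, sprintf("feat%02d", 1:10))
  expect_equal(sort(unique(sel$log$reason)), c("correlated", "low_variance"))
  # idempotence
  sel2 <- select_features(x[, sel$retained])
  expect_equal(sort(sel2$retained), sort(sel$retained))
  expect_equal(nrow(sel2$log), 0)
  # retained set has no violating pair
  cr <- stats::cor(x[, sel$retained]); diag(cr) <- 0
  expect_lt(max(abs(cr)), 0.8)
  # retained + removed partition the input
  expect_setequal(c(sel$retained, sel$removed), colnames(x))
})

test_that("group comparison reproduces the pooled t-test closed form", {
  x <- matrix(c(1, 2, 3, 2, 3, 4), ncol = 1,
              dimnames = list(NULL, "f"))
  labels <- c(1, 1, 1, 0, 0, 0)
  gc <- compare_groups(x, labels)
  expect_equal(gc$t, -1.224745, tolerance = 1e-6)
  expect_equal(gc$p, 2 * pt(-abs(gc$t), 4), tolerance = 1e-10)
  expect_equal(gc$p, 0.2879, tolerance = 1e-3)
  expect_equal(gc$mean_pcr, 2)
  expect_equal(gc$sd_non_pcr, 1)
  # identical groups: t = 0, p = 1
  xi <- matrix(rep(c(5, 6, 7), 2), ncol = 1, dimnames = list(NULL, "f"))
  gci <- compare_groups(xi, labels)
  expect_equal(gci$t, 0, tolerance = 1e-12)
  expect_equal(gci$p, 1, tolerance = 1e-12)
  expect_error(compare_groups(x, c(1, 0, 0, 0, 0, 0)), "at least 2")
  # textbook closed form on random 2-to-10-element fixtures
  set.seed(4)
  for (k in 1:10) {
    na <- sample(2:10, 1); nb <- sample(2:10, 1)
    a <- rnorm(na); b <- rnorm(nb)
    xm <- matrix(c(a, b), ncol = 1, dimnames = list(NULL, "f"))
    gck <- compare_groups(xm, c(rep(1, na), rep(0, nb)))
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(gck$t, tstat, tolerance = 1e-10)
    expect_equal(gck$p, 2 * pt(-abs(tstat), na + nb - 2), tolerance = 1e-10)
  }
})

test_that("significant_features returns the sub-alpha rows ordered by p", {
  set.seed(10)
  x <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  labels <- rep(c(1, 0), 20)
  x[, 2] <- x[, 2] + labels * 3
  sig <- significant_features(compare_groups(x, labels))
  expect_true("f2" %in% sig$feature)
  expect_true(all(diff(sig$p) >= 0))
})
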