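# Balancing, LOOCV harness, classifiers, configuration comparison.

make_xy <- function(n = 24, p = 8, effect = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  x[, 1] <- x[, 1] + effect * y
  list(x = x, y = y)
}

test_that("balancing keeps all responders plus an equal random subset", {
  labels <- c(rep(1, 12), rep(0, 46))
  bal <- balance_cohort(labels, seed = 3)
  expect_equal(length(bal$idx), 24)
  expect_true(all(1:12 %in% bal$idx))
  expect_equal(sum(labels[bal$idx]), 12)
  expect_identical(bal$idx, balance_cohort(labels, seed = 3)$idx)
  expect_false(identical(bal$idx, balance_cohort(labels, seed = 4)$idx))
  # already balanced: identity
  expect_equal(balance_cohort(rep(c(1, 0), 5), seed = 1)$idx, 1:10)
  expect_error(balance_cohort(c(1, 1, 0), seed = 1), "majority")
})

test_that("confusion metrics follow their defining ratios", {
  cm <- structure(list(tp = 5, tn = 3, fp = 1, fn = 1),
                  class = "confusion_matrix")
  m <- confusion_metrics(cm)
  expect_equal(m[["accuracy"]], 80)
  expect_equal(m[["sensitivity"]], 100 * 5 / 6, tolerance = 1e-10)
  expect_equal(m[["specificity"]], 75)
  expect_equal(m[["error_rate"]], 20)
  # perfect diagonal
  mp <- confusion_metrics(structure(list(tp = 4, tn = 4, fp = 0, fn = 0),
                                    class = "confusion_matrix"))
  expect_equal(unname(mp), c(100, 100, 100, 0))
  # zero denominator reports NA, never silently 0
  mna <- confusion_metrics(structure(list(tp = 0, tn = 5, fp = 0, fn = 0),
                                     class = "confusion_matrix"))
  expect_true(is.na(mna[["sensitivity"]]))
  expect_equal(mna[["specificity"]], 100)
})

test_that("LOOCV runs n folds and never shows the held-out row to the fit", {
  d <- make_xy(n = 16, effect = 3)
  seen <- list()
  res <- loocv(d$x, d$y, "lda", seed = 1,
               fold_hook = function(fold, train_idx) {
                 seen[[fold]] <<- train_idx
               })
  expect_equal(res$n_folds, 16)
  expect_equal(length(res$predictions), 16)
  expect_equal(length(seen), 16)
  for (i in 1:16) {
    expect_false(i %in% seen[[i]])
    expect_equal(length(seen[[i]]), 15)
  }
  n <- res$confusion
  expect_equal(n$tp + n$fp + n$fn + n$tn, 16)
  expect_error(loocv(d$x[1:3, ], d$y[1:3], "lda"), "at least 4")
  expect_error(loocv(d$x, d$y, "mystery"), "unknown classifier")
})

test_that("every classifier family solves a linearly separable problem", {
  d <- make_xy(n = 20, p = 5, effect = 6, seed = 7)
  for (cl in classifier_ids()) {
    res <- loocv(d$x, d$y, cl, seed = 11)
    expect_gte(res$metrics[["accuracy"]], 90)
  }
  # LDA on a strongly separable fixture gives the full diagonal
  d <- make_xy(n = 20, p = 5, effect = 10, seed = 7)
  res <- loocv(d$x, d$y, "lda", seed = 1)
  expect_equal(res$metrics[["accuracy"]], 100)
  expect_equal(res$confusion$fp + res$confusion$fn, 0)
})

test_that("degenerate single-class training folds fall back to the majority", {
  x <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- c(1, 0, 0, 0, 0)
  res <- loocv(x, y, "rf", seed = 2)
  # when the lone responder is held out the fold is single-class
  expect_equal(as.character(res$predictions[1]), "non_pCR")
})

test_that("shrinkage discriminants match MASS on well-conditioned data at zero shrinkage", {
  skip_if_not_installed("MASS")
  set.seed(21)
  n <- 60
  y <- as_pcr_factor(rep(c(0, 1), each = n / 2))
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[y == "pCR", ] <- x[y == "pCR", ] + 1
  fit <- mpMRIpcr:::fit_shrinkage_da(x, y, pooled = TRUE, lambda = 0)
  mine <- mpMRIpcr:::predict_shrinkage_da(fit, x)
  mass <- as.character(predict(MASS::lda(x, y))$class)
  expect_equal(mine, mass)
  fitq <- mpMRIpcr:::fit_shrinkage_da(x, y, pooled = FALSE, lambda = 0)
  mineq <- mpMRIpcr:::predict_shrinkage_da(fitq, x)
  massq <- as.character(predict(MASS::qda(x, y))$class)
  expect_equal(mineq, massq)
})

test_that("Gaussian naive Bayes matches e1071 on well-behaved data", {
  skip_if_not_installed("e1071")
  set.seed(22)
  n <- 60
  y <- as_pcr_factor(rep(c(0, 1), each = n / 2))
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  x[y == "pCR", 1] <- x[y == "pCR", 1] + 1.5
  fit <- mpMRIpcr:::fit_gnb(x, y)
  mine <- mpMRIpcr:::predict_gnb(fit, x)
  ref <- as.character(predict(e1071::naiveBayes(x, y), x))
  expect_equal(mine, ref)
})

test_that("label permutation keeps LOOCV accuracy at chance (leakage guard)", {
  set.seed(31)
  accs <- sapply(1:30, function(k) {
    d <- make_xy(n = 16, p = 10, effect = 0, seed = 100 + k)
    loocv(d$x, sample(d$y), "lda", seed = k)$metrics[["accuracy"]]
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 3 * se + 5)
})

test_that("configuration comparison fills the full grid and ranks best models", {
  d <- make_xy(n = 30, p = 6, effect = 4, seed = 5)
  clinical <- matrix(rbinom(30 * 4, 1, 0.5), 30, 4,
                     dimnames = list(NULL, c("age_over_40", "premenopausal",
                                             "stage_iii", "grade_iii")))
  tables <- list(imaging = d$x, clinical = clinical,
                 combined = cbind(d$x, clinical))
  rep1 <- compare_configurations(tables, d$y, balance_seeds = 1L)
  expect_equal(nrow(rep1$grid), 30)               # 3 configurations x 10 families
  expect_equal(sort(unique(rep1$grid$configuration)),
               c("clinical", "combined", "imaging"))
  expect_equal(nrow(rep1$best), 3)
  expect_true(all(rep1$grid$tp + rep1$grid$fp + rep1$grid$fn + rep1$grid$tn == 30))
  expect_equal(rep1$grid$accuracy + rep1$grid$error_rate, rep(100, 30))
  # imaging signal dominates the weak clinical flags
  b <- rep1$best
  expect_gte(b$accuracy[b$configuration == "combined"],
             b$accuracy[b$configuration == "clinical"])
  # perfectly predictive clinical flags reach the ceiling
  clin2 <- clinical; clin2[, 1] <- d$y
  tables2 <- list(imaging = d$x, clinical = clin2,
                  combined = cbind(d$x, clin2))
  rep2 <- compare_configurations(tables2, d$y, balance_seeds = 1L,
                                 classifiers = "dt")
  expect_equal(max(rep2$grid$accuracy[rep2$grid$configuration == "clinical"]),
               100)
})
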