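#' Balance a cohort by random undersampling of the majority class
#'
#' Keeps every responder (pCR, the minority class) and draws a uniform
#' random subset of non-responders of equal size; deterministic given
#' `seed`. Already-balanced input is returned unchanged.
#'
#' @param labels binary pCR labels (0/1 or factor).
#' @param seed integer seed for the undersampling draw.
#' @return An object of class `balanced_dataset`: list with `idx` (row
#'   indices into the input), `n_per_class` and `seed`.
#' @export
balance_cohort <- function(labels, seed = 1L) {
  y <- as_pcr_factor(labels)
  pos <- which(y == "pCR")
  neg <- which(y == "non_pCR")
  stop_if(length(neg) < length(pos),
          "majority class smaller than minority; nothing to undersample")
  if (length(neg) == length(pos)) {
    idx <- sort(c(pos, neg))
  } else {
    set.seed(seed)
    idx <- sort(c(pos, sample(neg, length(pos))))
  }
  structure(list(idx = idx, n_per_class = length(pos), seed = seed),
            class = "balanced_dataset")
}

#' Confusion matrix from predictions
#'
#' @param truth,predicted factors (or 0/1) with positive class pCR.
#' @return An object of class `confusion_matrix`: list with counts `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as_pcr_factor(truth)
  predicted <- as_pcr_factor(predicted)
  structure(list(tp = sum(truth == "pCR" & predicted == "pCR"),
                 fp = sum(truth == "non_pCR" & predicted == "pCR"),
                 fn = sum(truth == "pCR" & predicted == "non_pCR"),
                 tn = sum(truth == "non_pCR" & predicted == "non_pCR")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Performance metrics of a confusion matrix
#'
#' Accuracy, sensitivity, specificity and error rate in percent, with the
#' positive class fixed to pCR. Ratios with a zero denominator are
#' reported as `NA` (never silently 0).
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector (percent): `accuracy`, `sensitivity`,
#'   `specificity`, `error_rate`.
#' @export
confusion_metrics <- function(cm) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  stop_if(n == 0, "empty confusion matrix")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- 100 * (cm$tp + cm$tn) / n
  c(accuracy = acc,
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    error_rate = 100 - acc)
}

#' Leave-one-out cross-validation of one classifier
#'
#' Exactly `n` folds of test size one. All fitting — including the
#' per-feature standardisation used by the scale-sensitive learners — sees
#' only the `n - 1` training rows of each fold. A training fold that
#' degenerates to a single class predicts its majority class.
#'
#' @param x numeric matrix (cases x features).
#' @param labels binary pCR labels.
#' @param classifier classifier id, see [classifier_ids()].
#' @param seed integer; fold `i` is fitted under seed `seed + i`.
#' @param fold_hook optional function called per fold as
#'   `fold_hook(fold, train_idx)` before fitting (instrumentation, e.g.
#'   fold-hygiene checks).
#' @return An object of class `loocv_result`: list with `predictions`,
#'   `truth`, `confusion` (a [confusion_matrix()]), `metrics` and
#'   `n_folds`.
#' @export
loocv <- function(x, labels, classifier, seed = 1L, fold_hook = NULL) {
  x <- as.matrix(x)
  y <- as_pcr_factor(labels)
  n <- nrow(x)
  stop_if(n < 4L, "need at least 4 cases for leave-one-out")
  stop_if(!classifier %in% classifier_ids(),
          sprintf("unknown classifier id '%s'", classifier))
  preds <- factor(rep(NA_character_, n), levels = pcr_levels())
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (!is.null(fold_hook)) fold_hook(i, tr)
    fit <- fit_classifier(classifier, x[tr, , drop = FALSE], y[tr],
                          seed = seed + i)
    preds[i] <- predict_classifier(fit, x[i, , drop = FALSE])
  }
  cm <- confusion_matrix(y, preds)
  structure(list(predictions = preds, truth = y, confusion = cm,
                 metrics = confusion_metrics(cm), n_folds = n),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d folds, accuracy %.1f%%\n",
              x$n_folds, x$metrics[["accuracy"]]))
  invisible(x)
}

#' Compare classifiers across the three feature configurations
#'
#' Balances the cohort, then runs leave-one-out cross-validation for every
#' classifier family on the imaging-only, clinical-only and combined
#' feature views, producing the full configurations-by-classifiers grid of
#' confusion matrices and metrics. With several `balance_seeds` the grid
#' is repeated per undersampling draw (one draw of 12 from 46 is
#' high-variance, so a multi-seed mode reports that dispersion).
#'
#' @param tables named list of numeric matrices (`imaging`, `clinical`,
#'   `combined`), all with the same rows.
#' @param labels binary pCR labels, one per row.
#' @param balance_seeds integer vector of undersampling seeds (default 1).
#' @param classifiers classifier ids (default all ten).
#' @param loocv_seed base seed for the per-fold fits.
#' @return An object of class `comparison_report`: data frame `grid` with
#'   one row per (balance seed, configuration, classifier) holding the
#'   confusion counts and metrics, plus `best` (best classifier per
#'   configuration and seed by accuracy; ties broken by fewer false
#'   negatives, then classifier name).
#' @export
compare_configurations <- function(tables, labels,
                                   balance_seeds = 1L,
                                   classifiers = classifier_ids(),
                                   loocv_seed = 100L) {
  stop_if(!all(c("imaging", "clinical", "combined") %in% names(tables)),
          "tables must contain imaging, clinical and combined views")
  nr <- unique(vapply(tables, nrow, integer(1)))
  stop_if(length(nr) != 1L || nr != length(labels),
          "tables and labels must cover the same patients")
  rows <- list()
  for (bs in balance_seeds) {
    bal <- balance_cohort(labels, seed = bs)
    yb <- as_pcr_factor(labels)[bal$idx]
    for (cfg in c("imaging", "clinical", "combined")) {
      xb <- tables[[cfg]][bal$idx, , drop = FALSE]
      for (cl in classifiers) {
        res <- loocv(xb, yb, cl, seed = loocv_seed)
        cm <- res$confusion
        rows[[length(rows) + 1L]] <- data.frame(
          balance_seed = bs, configuration = cfg, classifier = cl,
          tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
          accuracy = res$metrics[["accuracy"]],
          sensitivity = res$metrics[["sensitivity"]],
          specificity = res$metrics[["specificity"]],
          error_rate = res$metrics[["error_rate"]])
      }
    }
  }
  grid <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(grid,
                                      grid[c("balance_seed", "configuration")],
                                      drop = TRUE), function(g) {
    g <- g[order(-g$accuracy, g$fn, g$classifier), , drop = FALSE]
    g[1L, , drop = FALSE]
  }))
  rownames(best) <- NULL
  structure(list(grid = grid, best = best,
                 n_per_class = balance_cohort(labels,
                                              balance_seeds[1L])$n_per_class),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d grid cells over %d balancing seed(s)\n",
              nrow(x$grid), length(unique(x$grid$balance_seed))))
  b <- x$best[x$best$balance_seed == x$best$balance_seed[1L], ]
  for (k in seq_len(nrow(b))) {
    cat(sprintf("  best %-9s %-9s accuracy %5.1f%%\n",
                b$configuration[k], b$classifier[k], b$accuracy[k]))
  }
  invisible(x)
}
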