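#' ROI summary statistics of a voxel map
#'
#' Mean, median, standard deviation and 25th/75th percentiles over the
#' valid (finite) masked voxels; percentiles use the linear-interpolation
#' convention (R type 7).
#'
#' @param map numeric 3D array.
#' @param mask logical 3D array on the same grid.
#' @return named numeric vector `c(mean, median, std, p25, p75)`.
#' @export
roi_statistics <- function(map, mask) {
  stop_if(!identical(dim(map), dim(mask)), "map and mask grids differ")
  stop_if(!any(mask), "empty mask")
  v <- map[mask]
  v <- v[is.finite(v)]
  stop_if(length(v) == 0L, "no valid masked voxel")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(v),
    median = q[2L],
    std = if (length(v) > 1L) stats::sd(v) else 0,
    p25 = q[1L],
    p75 = q[3L])
}

biomarker_names <- function() {
  c("iAUC60", "slope", "peak", "TTP", "ADC", "D", "D_star", "f")
}

#' Per-patient imaging feature vector
#'
#' Runs the perfusion and diffusion voxel-wise extraction on one patient
#' and summarises: 8 biomarkers x 5 ROI statistics (40 columns, named
#' `<biomarker>_<stat>`, e.g. `TTP_p25`, `D_star_std`) plus the 211
#' radiomic features of [extract_radiomics()] on the fitted ADC and iAUC60
#' maps, for 251 imaging features.
#'
#' @param patient one element of a [generate_cohort()] (or any list with
#'   `dce`, `dwi`, `mask`).
#' @param config a [radiomics_config()].
#' @param relaxivity_scale passed to [perfusion_maps()].
#' @param b_threshold passed to [diffusion_maps()].
#' @return named numeric vector of 251 imaging features.
#' @export
extract_features <- function(patient, config = radiomics_config(),
                             relaxivity_scale = 1, b_threshold = 200) {
  perf <- perfusion_maps(patient$dce, patient$mask,
                         relaxivity_scale = relaxivity_scale)
  dmaps <- diffusion_maps(patient$dwi, patient$mask, b_threshold = b_threshold)
  maps <- list(iAUC60 = perf$iauc60, slope = perf$initial_slope,
               peak = perf$peak, TTP = perf$ttp,
               ADC = dmaps$adc, D = dmaps$d, D_star = dmaps$dstar, f = dmaps$f)
  stats40 <- unlist(lapply(names(maps), function(nm) {
    s <- roi_statistics(maps[[nm]], patient$mask)
    stats::setNames(s, paste0(nm, "_", names(s)))
  }))
  rad <- extract_radiomics(list(adc = dmaps$adc, iauc60 = perf$iauc60),
                           patient$mask, config = config,
                           spacing = patient$dce$spacing)
  c(stats40, rad)
}

#' Assemble the per-patient feature table
#'
#' Combines imaging features, the four binary clinical covariates and the
#' pCR labels into a single table with per-column provenance, from which
#' the three model configurations (imaging-only, clinical-only, combined)
#' are derived views.
#'
#' @param imaging numeric matrix or data frame of imaging features
#'   (patients x features), rownames = patient ids.
#' @param clinical numeric matrix or data frame of the four binary clinical
#'   covariates, same patients.
#' @param labels binary pCR labels (0/1), one per patient.
#' @param patient_ids character ids; defaults to the imaging rownames.
#' @return An object of class `feature_table`.
#' @export
assemble_feature_table <- function(imaging, clinical, labels,
                                   patient_ids = rownames(imaging)) {
  imaging <- as.matrix(imaging)
  clinical <- as.matrix(clinical)
  stop_if(is.null(patient_ids), "patient ids are required")
  stop_if(anyDuplicated(patient_ids) > 0, "duplicate patient id")
  stop_if(nrow(imaging) != length(patient_ids) ||
            nrow(clinical) != length(patient_ids) ||
            length(labels) != length(patient_ids),
          "a patient is missing a modality, labels or ids")
  stop_if(any(!is.finite(imaging)) || any(!is.finite(clinical)),
          "missing values in the assembled table")
  nms <- c(colnames(imaging), colnames(clinical))
  stop_if(anyDuplicated(nms) > 0, "feature names must be unique")
  x <- cbind(imaging, clinical)
  rownames(x) <- patient_ids
  structure(list(
    x = x,
    labels = as.integer(labels),
    provenance = c(rep("imaging", ncol(imaging)),
                   rep("clinical", ncol(clinical)))),
    class = "feature_table")
}

#' Extract a model-configuration view from a feature table
#'
#' @param table a [assemble_feature_table()] result.
#' @param view `"imaging"`, `"clinical"` or `"combined"`.
#' @return numeric matrix (patients x features).
#' @export
feature_view <- function(table, view = c("imaging", "clinical", "combined")) {
  view <- match.arg(view)
  stop_if(!inherits(table, "feature_table"), "not a feature_table")
  keep <- switch(view,
                 imaging = table$provenance == "imaging",
                 clinical = table$provenance == "clinical",
                 combined = rep(TRUE, length(table$provenance)))
  table$x[, keep, drop = FALSE]
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features (%d imaging, %d clinical), %d pCR\n",
              nrow(x$x), ncol(x$x), sum(x$provenance == "imaging"),
              sum(x$provenance == "clinical"), sum(x$labels == 1L)))
  invisible(x)
}

minmax_scale <- function(x) {
  rng <- apply(x, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  sweep(sweep(x, 2L, rng[1L, ]), 2L, span, "/")
}

#' Low-variance feature filter
#'
#' Removes every column whose sample variance is at or below `threshold`
#' (inclusive). The variance is computed on raw values by default — the
#' threshold then acts in each feature's own units, which eliminates
#' whole families of small-magnitude features (diffusion coefficients,
#' fractions of unity) while keeping large-unit ones; see the methods
#' vignette for why this literal reading is the default and what the
#' alternatives do. `scaling = "minmax"` rescales each column to [0, 1]
#' first (note a Gaussian column then has variance ~0.06, so a 0.1
#' threshold removes nearly everything); `scaling = "zscore"` standardises
#' columns, making the filter a no-op except for constant columns.
#'
#' @param x numeric matrix (patients x features).
#' @param threshold variance threshold (default 0.1).
#' @param scaling `"raw"` (default), `"minmax"` or `"zscore"`.
#' @return list with `retained` (names), `removed` (names) and `log`
#'   (data frame: name, reason, detail).
#' @export
variance_filter <- function(x, threshold = 0.1,
                            scaling = c("raw", "minmax", "zscore")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  xs <- switch(scaling,
               raw = x,
               minmax = minmax_scale(x),
               zscore = {
                 s <- scale(x)
                 s[, apply(x, 2L, stats::sd) == 0] <- 0
                 s
               })
  v <- apply(xs, 2L, stats::var)
  drop <- v <= threshold
  stop_if(all(drop),
          "variance filter removed every column; review the threshold")
  nd <- sum(drop)
  list(retained = colnames(x)[!drop],
       removed = colnames(x)[drop],
       log = data.frame(name = colnames(x)[drop],
                        reason = rep("low_variance", nd),
                        partner = rep(NA_character_, nd),
                        r = rep(NA_real_, nd),
                        detail = sprintf("var=%.4g (%s)", v[drop], scaling)))
}

#' Correlation-redundancy filter
#'
#' Greedy elimination of correlated pairs: pairs with `|Pearson r|` above
#' `threshold` are visited in order of descending `|r|` and the
#' lower-raw-variance member of each pair is dropped (ties broken by
#' lexicographic name order), until no violating pair remains among the
#' retained columns.
#'
#' @param x numeric matrix (patients x features).
#' @param threshold correlation threshold (default 0.8).
#' @return list with `retained`, `removed` and `log` as in
#'   [variance_filter()].
#' @export
correlation_filter <- function(x, threshold = 0.8) {
  x <- as.matrix(x)
  nms <- colnames(x)
  v <- apply(x, 2L, stats::var)
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  pairs <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
  logs <- list()
  if (nrow(pairs)) {
    ord <- order(-abs(cm[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    alive <- rep(TRUE, ncol(x))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1L]; b <- pairs[k, 2L]
      if (!alive[a] || !alive[b]) next
      # keep the higher-variance member; lexicographic tie-break
      drop <- if (v[a] > v[b]) b
              else if (v[b] > v[a]) a
              else if (nms[a] <= nms[b]) b else a
      keep <- if (drop == a) b else a
      alive[drop] <- FALSE
      logs[[length(logs) + 1L]] <- data.frame(
        name = nms[drop], reason = "correlated", partner = nms[keep],
        r = cm[a, b], detail = sprintf("|r|=%.3f", abs(cm[a, b])))
    }
    retained <- nms[alive]
  } else retained <- nms
  list(retained = retained,
       removed = setdiff(nms, retained),
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(name = character(0), reason = character(0),
                    partner = character(0), r = numeric(0),
                    detail = character(0)))
}

#' Two-step feature selection
#'
#' Composes the low-variance filter and the correlation-redundancy filter,
#' returning the retained feature names and the full removal log. The
#' result is idempotent and the retained set contains no pair with
#' `|r|` above the correlation threshold.
#'
#' @param x numeric matrix (patients x features).
#' @param var_threshold variance threshold (default 0.1).
#' @param cor_threshold correlation threshold (default 0.8).
#' @param scaling variance-filter scaling, see [variance_filter()].
#' @return An object of class `selection_result`: list with `retained`,
#'   `removed` and `log`.
#' @export
select_features <- function(x, var_threshold = 0.1, cor_threshold = 0.8,
                            scaling = c("raw", "minmax", "zscore")) {
  x <- as.matrix(x)
  s1 <- variance_filter(x, var_threshold, scaling)
  s2 <- correlation_filter(x[, s1$retained, drop = FALSE], cor_threshold)
  structure(list(retained = s2$retained,
                 removed = c(s1$removed, s2$removed),
                 log = rbind(s1$log, s2$log)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d retained, %d removed (%d low-variance, %d correlated)\n",
              length(x$retained), length(x$removed),
              sum(x$log$reason == "low_variance"),
              sum(x$log$reason == "correlated")))
  invisible(x)
}

#' Per-feature group comparison (Student's t-test)
#'
#' Two-sample pooled-variance t-test of every feature between responders
#' (pCR) and non-responders, reported in the style of the published
#' group-comparison table: group mean (SD) for each group, the t statistic
#' and the two-sided p-value. No multiple-testing correction is applied
#' (the emulated analysis reports unadjusted p < 0.05); the returned
#' object flags this.
#'
#' @param x numeric matrix (patients x features).
#' @param labels binary pCR labels (0/1 or logical).
#' @return An object of class `group_comparison`: data frame with columns
#'   `feature`, `mean_pcr`, `sd_pcr`, `mean_non_pcr`, `sd_non_pcr`, `t`,
#'   `p`, plus attributes `n_pcr`, `n_non_pcr`,
#'   `multiple_testing = "none"`.
#' @export
compare_groups <- function(x, labels) {
  x <- as.matrix(x)
  g <- as.integer(labels)
  stop_if(length(g) != nrow(x), "labels do not match rows")
  stop_if(sum(g == 1L) < 2L || sum(g == 0L) < 2L,
          "each group needs at least 2 members")
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[g == 1L, j]; b <- x[g == 0L, j]
    if (stats::var(a) + stats::var(b) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    data.frame(feature = colnames(x)[j],
               mean_pcr = mean(a), sd_pcr = stats::sd(a),
               mean_non_pcr = mean(b), sd_non_pcr = stats::sd(b),
               t = unname(tt$statistic), p = unname(tt$p.value))
  })
  out <- do.call(rbind, res)
  attr(out, "n_pcr") <- sum(g == 1L)
  attr(out, "n_non_pcr") <- sum(g == 0L)
  attr(out, "multiple_testing") <- "none"
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Significant rows of a group comparison
#'
#' @param comparison a [compare_groups()] result.
#' @param alpha significance level (default 0.05, unadjusted).
#' @return the significant subset, ordered by p-value.
#' @export
significant_features <- function(comparison, alpha = 0.05) {
  out <- comparison[comparison$p < alpha, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
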