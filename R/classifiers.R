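# The ten classifier families compared by the response models, behind one
# fit/predict interface. Labels are a factor with levels
# c("non_pCR", "pCR"); the positive class is "pCR".
#
# Hyperparameters are fixed (no tuning) and every stochastic learner is
# seeded by the caller; scale-sensitive learners (k-NN, MLP, logistic
# ridge, LDA, QDA) are z-scored per feature on the training fold only.

pcr_levels <- function() c("non_pCR", "pCR")

as_pcr_factor <- function(labels) {
  if (is.factor(labels)) {
    stop_if(!all(levels(labels) %in% pcr_levels()), "unknown label levels")
    factor(as.character(labels), levels = pcr_levels())
  } else {
    factor(ifelse(as.integer(labels) == 1L, "pCR", "non_pCR"),
           levels = pcr_levels())
  }
}

#' Names of the supported classifier families
#'
#' k-nearest neighbours, decision tree, random forest, AdaBoost, gradient
#' boosting, Gaussian naive Bayes, linear and quadratic discriminant
#' analysis (with covariance shrinkage), multi-layer perceptron and
#' (ridge-penalised) logistic regression.
#'
#' @return character vector of classifier ids.
#' @export
classifier_ids <- function() {
  c("knn", "dt", "rf", "adaboost", "gboost", "gnb", "lda", "qda", "mlp", "lr")
}

scaled_classifiers <- function() c("knn", "mlp", "lr", "lda", "qda")

#' Fit one classifier
#'
#' @param id classifier id, see [classifier_ids()].
#' @param x numeric training matrix (rows = cases).
#' @param y labels (0/1 or factor with levels `non_pCR`/`pCR`).
#' @param seed integer seed applied before fitting (stochastic learners).
#' @return An object of class `pcr_classifier` for [predict_classifier()].
#' @export
fit_classifier <- function(id, x, y, seed = 1L) {
  stop_if(!id %in% classifier_ids(), sprintf("unknown classifier id '%s'", id))
  x <- as.matrix(x)
  y <- as_pcr_factor(y)
  set.seed(seed)
  scaling <- NULL
  if (id %in% scaled_classifiers()) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    scaling <- list(center = ctr, scale = scl)
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  }
  if (length(unique(y)) < 2L) {
    # degenerate fold: predict the training-fold majority
    fit <- list(majority = names(which.max(table(y))))
    return(structure(list(id = "majority", fit = fit, scaling = scaling),
                     class = "pcr_classifier"))
  }
  fit <- switch(id,
    knn = list(x = x, y = y, k = 5L),
    dt = rpart::rpart(y ~ ., data = data.frame(x, y = y), method = "class",
                      control = rpart::rpart.control(minsplit = 4L, cp = 0.01,
                                                     xval = 0L)),
    rf = randomForest::randomForest(x, y, ntree = 200L),
    adaboost = fit_adaboost(x, y, n_rounds = 30L),
    gboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 2L,
                    eta = 0.3, nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y == "pCR"),
                                  nthread = 1L),
      nrounds = 30L),
    gnb = fit_gnb(x, y),
    lda = fit_shrinkage_da(x, y, pooled = TRUE, lambda = 0.2),
    qda = fit_shrinkage_da(x, y, pooled = FALSE, lambda = 0.5),
    mlp = nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2L, drop = FALSE],
                     size = 4L, decay = 0.1, maxit = 200L, trace = FALSE,
                     entropy = TRUE),
    lr = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = 0.05, standardize = FALSE))
  structure(list(id = id, fit = fit, scaling = scaling),
            class = "pcr_classifier")
}

#' Predict with a fitted classifier
#'
#' @param object a [fit_classifier()] result.
#' @param x numeric matrix of cases to classify.
#' @return factor of predictions with levels `non_pCR`/`pCR`.
#' @export
predict_classifier <- function(object, x) {
  stop_if(!inherits(object, "pcr_classifier"), "not a pcr_classifier")
  x <- as.matrix(x)
  if (!is.null(object$scaling)) {
    x <- sweep(sweep(x, 2L, object$scaling$center), 2L,
               object$scaling$scale, "/")
  }
  fit <- object$fit
  pred <- switch(object$id,
    majority = rep(fit$majority, nrow(x)),
    knn = as.character(class::knn(fit$x, x, fit$y, k = fit$k)),
    dt = as.character(predict(fit, data.frame(x), type = "class")),
    rf = as.character(predict(fit, x)),
    adaboost = predict_adaboost(fit, x),
    gboost = ifelse(predict(fit, x) > 0.5, "pCR", "non_pCR"),
    gnb = predict_gnb(fit, x),
    lda = predict_shrinkage_da(fit, x),
    qda = predict_shrinkage_da(fit, x),
    mlp = ifelse(predict(fit, x) > 0.5, "pCR", "non_pCR"),
    lr = as.character(predict(fit, x, type = "class")))
  factor(pred, levels = pcr_levels())
}

# --- Gaussian naive Bayes with a per-feature variance floor -----------------
# The floor keeps densities defined when a feature is constant within one
# class (routine for binary clinical flags on 11-row training folds).

fit_gnb <- function(x, y) {
  classes <- levels(y)
  pooled <- apply(x, 2L, stats::var)
  floor_var <- pmax(1e-3 * pooled, 1e-9)
  stats_by <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xi),
         var = pmax(apply(xi, 2L, stats::var), floor_var),
         logprior = log(nrow(xi) / nrow(x)))
  })
  names(stats_by) <- classes
  list(classes = classes, stats = stats_by)
}

predict_gnb <- function(fit, x) {
  x <- as.matrix(x)
  ll <- vapply(fit$classes, function(cl) {
    s <- fit$stats[[cl]]
    dens <- matrix(stats::dnorm(rep(t(x), 1),
                                mean = rep(s$mean, times = nrow(x)),
                                sd = sqrt(rep(s$var, times = nrow(x))),
                                log = TRUE),
                   nrow = nrow(x), byrow = TRUE)
    rowSums(dens) + s$logprior
  }, numeric(nrow(x)))
  ll <- matrix(ll, nrow = nrow(x))
  fit$classes[max.col(ll, ties.method = "first")]
}

# --- Shrinkage discriminant analysis ----------------------------------------
# Gaussian discriminants with covariance shrinkage towards a scaled
# identity: pooled covariance (LDA) or per-class covariance (QDA). With 24
# balanced cases and ~40 features the sample covariances are singular, so
# a fixed shrinkage weight keeps the discriminant defined; lambda = 0
# recovers textbook LDA/QDA on well-conditioned data.

fit_shrinkage_da <- function(x, y, pooled = TRUE, lambda = 0.2) {
  classes <- levels(droplevels(y))
  p <- ncol(x)
  mu <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  names(mu) <- classes
  shrink <- function(S) {
    S <- (1 - lambda) * S + lambda * mean(diag(S)) * diag(p)
    # guard against numerically zero spectra
    S + 1e-10 * mean(diag(S)) * diag(p)
  }
  if (pooled) {
    Sp <- Reduce(`+`, lapply(classes, function(cl) {
      xi <- x[y == cl, , drop = FALSE]
      crossprod(sweep(xi, 2L, mu[[cl]]))
    })) / (nrow(x) - length(classes))
    Ss <- list(shrink(Sp))[rep(1L, length(classes))]
  } else {
    Ss <- lapply(classes, function(cl) {
      xi <- x[y == cl, , drop = FALSE]
      shrink(stats::cov(xi))
    })
  }
  names(Ss) <- classes
  prec <- lapply(Ss, function(S) {
    R <- chol(S)
    list(inv = chol2inv(R), logdet = 2 * sum(log(diag(R))))
  })
  priors <- table(y)[classes] / length(y)
  list(classes = classes, mu = mu, prec = prec,
       logprior = log(as.numeric(priors)))
}

predict_shrinkage_da <- function(fit, x) {
  scores <- sapply(seq_along(fit$classes), function(k) {
    d <- sweep(x, 2L, fit$mu[[k]])
    q <- rowSums((d %*% fit$prec[[k]]$inv) * d)
    -0.5 * fit$prec[[k]]$logdet - 0.5 * q + fit$logprior[k]
  })
  scores <- matrix(scores, ncol = length(fit$classes))
  fit$classes[max.col(scores, ties.method = "first")]
}

# --- AdaBoost.M1 over decision stumps ---------------------------------------
# The weak learner is a weighted decision stump found by exhaustive
# threshold search (both polarities), vectorised with weight cumsums.

best_stump <- function(x, ysign, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xv <- x[ord, j]
    wy <- (w * ysign)[ord]
    # classify "pCR if x > thr": err = P(+1 & x <= thr) + P(-1 & x > thr)
    wpos <- ifelse(wy > 0, wy, 0)
    wneg <- ifelse(wy < 0, -wy, 0)
    err_gt <- cumsum(wpos) + (sum(wneg) - cumsum(wneg))
    err_le <- 1 - err_gt                     # opposite polarity
    k <- seq_along(xv)
    usable <- k < length(xv) & xv < c(xv[-1L], Inf)  # split between distinct values
    if (!any(usable)) next
    for (polarity in c(1, -1)) {
      e <- if (polarity > 0) err_gt else err_le
      e[!usable] <- Inf
      kbest <- which.min(e)
      if (e[kbest] < best$err) {
        best <- list(err = e[kbest], feature = j,
                     threshold = (xv[kbest] + xv[kbest + 1L]) / 2,
                     polarity = polarity)
      }
    }
  }
  best
}

predict_stump <- function(stump, x) {
  gt <- x[, stump$feature] > stump$threshold
  if (stump$polarity > 0) ifelse(gt, 1, -1) else ifelse(gt, -1, 1)
}

fit_adaboost <- function(x, y, n_rounds = 30L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  ysign <- ifelse(y == "pCR", 1, -1)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    stump <- best_stump(x, ysign, w)
    if (!is.finite(stump$err)) break
    pred <- predict_stump(stump, x)
    miss <- pred != ysign
    err <- sum(w[miss])
    if (err <= 1e-10) {           # perfect stump: give it a large vote
      stumps[[length(stumps) + 1L]] <- stump
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break         # no better than chance under these weights
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(miss, 1, -1))
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {     # fall back to the majority class
    return(list(majority = names(which.max(table(y)))))
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, x) {
  if (!is.null(fit$majority)) return(rep(fit$majority, nrow(x)))
  score <- rep(0, nrow(x))
  for (m in seq_along(fit$stumps)) {
    score <- score + fit$alphas[m] * predict_stump(fit$stumps[[m]], x)
  }
  ifelse(score > 0, "pCR", "non_pCR")
}
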