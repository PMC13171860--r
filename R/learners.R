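# Supervised learner registry. Six base learners (the registry ids mirror
# the algorithm families compared in the study) plus diagnostic helpers.
# All tree learners share one CART core (src/trees.cpp); the boosted ids are
# distinct, documented gradient-boosting configurations rather than bindings
# to the eponymous libraries (none of which is available offline):
#   gbdt     -- classical depth-3 gradient boosting, full rows/features
#   xgboost  -- depth-4 boosting with row subsample 0.8, feature subsample 0.8
#   lightgbm -- depth-6 boosting, larger min leaf (20), feature subsample 0.8
# Defaults are deliberately fixed and overridable; no tuning is attempted.

#' Supported learner ids and their default hyperparameters
#' @return Named list of default parameter lists.
#' @export
learner_registry <- function() {
  list(
    rf       = list(n_trees = 500, max_depth = 25, min_leaf = 5,
                    mtry_frac = 1 / 3),
    xgboost  = list(rounds = 500, lr = 0.05, max_depth = 4, min_leaf = 5,
                    subsample = 0.8, colsample = 0.8),
    gbdt     = list(rounds = 500, lr = 0.05, max_depth = 3, min_leaf = 10,
                    subsample = 1, colsample = 1),
    adaboost = list(n_estimators = 50, max_depth = 4, min_leaf = 5),
    knn      = list(k = 5),
    lightgbm = list(rounds = 500, lr = 0.05, max_depth = 6, min_leaf = 20,
                    subsample = 1, colsample = 0.8),
    mean     = list()   # predicts the training mean; diagnostic baseline
  )
}

as_X <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' Fit a registered learner
#'
#' @param id Learner id (see [learner_registry()]).
#' @param X Numeric predictor matrix / data.frame.
#' @param y Numeric response.
#' @param params Overrides of the registry defaults.
#' @param seed Integer seed controlling every stochastic element.
#' @return Object of class `cs_learner`.
#' @export
fit_learner <- function(id, X, y, params = list(), seed = 1) {
  reg <- learner_registry()
  if (!id %in% names(reg))
    stop_schema("unknown learner id '%s' (registry: %s)", id,
                paste(names(reg), collapse = ", "))
  p <- reg[[id]]
  p[names(params)] <- params
  X <- as_X(X)
  n <- nrow(X); np <- ncol(X)
  fit <- with_seed(seed, switch(id,
    rf = {
      mtry <- max(1L, floor(np * p$mtry_frac))
      trees <- lapply(seq_len(p$n_trees), function(b) {
        rows <- sample.int(n, n, replace = TRUE) - 1L
        cs_tree_fit(X, y, rows, p$max_depth, p$min_leaf, mtry,
                    sample.int(2^30, 1))
      })
      list(trees = trees)
    },
    xgboost = ,
    gbdt = ,
    lightgbm = {
      # optional offset boosting (the base_margin mechanism): start from an
      # input column instead of the global mean, so the rounds learn only
      # the correction -- used by stack meta-learners on near-identity
      # meta-features
      offset <- if (!is.null(p$init_col)) X[, p$init_col] else 0
      f0 <- mean(y - offset)
      resid <- y - offset - f0
      mtry <- max(1L, floor(np * p$colsample))
      trees <- vector("list", p$rounds)
      for (b in seq_len(p$rounds)) {
        rows <- if (p$subsample < 1)
          sample.int(n, max(2L, floor(p$subsample * n))) - 1L
        else seq_len(n) - 1L
        tr <- cs_tree_fit(X, resid, rows, p$max_depth, p$min_leaf, mtry,
                          sample.int(2^30, 1))
        resid <- resid - p$lr * cs_tree_predict(tr, X)
        trees[[b]] <- tr
      }
      list(f0 = f0, lr = p$lr, trees = trees, init_col = p$init_col)
    },
    adaboost = {
      # AdaBoost.R2 with linear loss and weighted-median aggregation
      w <- rep(1 / n, n)
      trees <- list(); betas <- numeric(0)
      for (b in seq_len(p$n_estimators)) {
        rows <- sample.int(n, n, replace = TRUE, prob = w) - 1L
        tr <- cs_tree_fit(X, y, rows, p$max_depth, p$min_leaf, np,
                          sample.int(2^30, 1))
        pred <- cs_tree_predict(tr, X)
        err <- abs(pred - y)
        emax <- max(err)
        if (emax < 1e-12) { trees <- c(trees, list(tr)); betas <- c(betas, 1e-10); break }
        L <- err / emax
        Lbar <- sum(w * L)
        if (Lbar >= 0.5) { if (length(trees) == 0) { trees <- list(tr); betas <- 1 }; break }
        beta <- Lbar / (1 - Lbar)
        trees <- c(trees, list(tr)); betas <- c(betas, beta)
        w <- w * beta^(1 - L)
        w <- w / sum(w)
      }
      list(trees = trees, log_inv_beta = log(1 / betas))
    },
    knn = {
      mu <- colMeans(X)
      sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
      list(k = p$k, mu = mu, sd = sdv,
           Xs = sweep(sweep(X, 2, mu), 2, sdv, "/"), y = y)
    },
    mean = list(mu = mean(y))
  ))
  structure(list(id = id, params = p, fit = fit, seed = seed,
                 feature_names = colnames(X)),
            class = "cs_learner")
}

#' Predict from a fitted learner
#' @param object A `cs_learner`.
#' @param newdata Matrix / data.frame with the training columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.cs_learner <- function(object, newdata, ...) {
  X <- as_X(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(X)))
      stop_schema("newdata lacks columns: %s",
                  paste(setdiff(object$feature_names, colnames(X)),
                        collapse = ", "))
    X <- X[, object$feature_names, drop = FALSE]
  }
  f <- object$fit
  switch(object$id,
    rf = {
      preds <- vapply(f$trees, function(tr) cs_tree_predict(tr, X),
                      numeric(nrow(X)))
      if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
    },
    xgboost = , gbdt = , lightgbm = {
      out <- rep(f$f0, nrow(X))
      if (!is.null(f$init_col)) out <- out + X[, f$init_col]
      for (tr in f$trees) out <- out + f$lr * cs_tree_predict(tr, X)
      out
    },
    adaboost = {
      P <- vapply(f$trees, function(tr) cs_tree_predict(tr, X),
                  numeric(nrow(X)))
      if (nrow(X) == 1L) P <- matrix(P, nrow = 1)
      w <- f$log_inv_beta
      apply(P, 1, function(row) weighted_median(row, w))
    },
    knn = {
      Xs <- sweep(sweep(X, 2, f$mu), 2, f$sd, "/")
      k <- min(f$k, nrow(f$Xs))
      apply(Xs, 1, function(r) {
        d <- sqrt(colSums((t(f$Xs) - r)^2))
        mean(f$y[order(d)[seq_len(k)]])
      })
    },
    mean = rep(f$mu, nrow(X))
  )
}

weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  if (sum(w) <= 0) return(median(x))
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' SHAP values for a fitted tree learner
#'
#' Exact tree-path SHAP (path-dependent feature perturbation) summed over
#' the ensemble. Satisfies local accuracy: per row, the contributions plus
#' the expected value reproduce the model prediction.
#'
#' @param object A `cs_learner` of id `rf`, `gbdt`, `xgboost` or `lightgbm`.
#' @param X Rows to explain.
#' @return List with `shap` (n x p matrix) and `base` (scalar expected
#'   value); `rowSums(shap) + base` equals `predict(object, X)`.
#' @export
shap_values <- function(object, X) {
  stopifnot(inherits(object, "cs_learner"))
  X <- as_X(X)
  if (!is.null(object$feature_names) && !is.null(colnames(X)))
    X <- X[, object$feature_names, drop = FALSE]
  p <- ncol(X)
  f <- object$fit
  if (object$id == "rf") {
    acc <- matrix(0, nrow(X), p + 1)
    for (tr in f$trees) acc <- acc + cs_tree_shap(tr, X)
    acc <- acc / length(f$trees)
  } else if (object$id %in% c("gbdt", "xgboost", "lightgbm")) {
    if (!is.null(object$fit$init_col))
      stop("SHAP not defined for offset-initialized boosters")
    acc <- matrix(0, nrow(X), p + 1)
    for (tr in f$trees) acc <- acc + f$lr * cs_tree_shap(tr, X)
    acc[, p + 1] <- acc[, p + 1] + f$f0
  } else stop("SHAP is implemented for tree learners only")
  shap <- acc[, seq_len(p), drop = FALSE]
  colnames(shap) <- colnames(X)
  list(shap = shap, base = acc[1, p + 1], base_per_row = acc[, p + 1])
}
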