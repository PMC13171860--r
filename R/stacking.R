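# Multi-level stacking ensemble: six base learners -> out-of-fold meta
# features -> two meta-learners on the two best base models -> one final
# meta-learner; plus the pass-through baseline that forwards the raw
# concatenated meta-features straight to the final learner.

#' Specify the stacking topology
#'
#' @param level0 Character vector of base learner ids (default the six
#'   registered: rf, xgboost, gbdt, adaboost, knn, lightgbm).
#' @param level0_params Named list of per-learner hyperparameter overrides.
#' @param oof_folds Cross-validation folds for the meta features (default
#'   10).
#' @param level1 Two meta-learner ids (default both `lightgbm`, kept
#'   distinct by seed and depth).
#' @param level1_params List of two override lists. Meta-learners operate on
#'   one or two strongly predictive meta-feature columns, so the defaults
#'   are deliberately weak and regularized (100 shallow rounds, large
#'   leaves): an aggressive booster at this level mostly refits the
#'   out-of-fold noise of the base predictions and degrades the stack.
#' @param level2 Final meta-learner id (default `lightgbm`).
#' @param level2_params Overrides for the final learner (same weak default
#'   rationale as level-1).
#' @param level1_input `"top2"` (default: meta-learners see the OOF columns
#'   of the two best base models) or `"all"`.
#' @param seed Integer seed; all randomness in the stack derives from it.
#' @return List of class `cs_stack_spec`.
#' @export
stack_spec <- function(level0 = c("rf", "xgboost", "gbdt", "adaboost",
                                  "knn", "lightgbm"),
                       level0_params = list(), oof_folds = 10,
                       level1 = c("lightgbm", "lightgbm"),
                       level1_params = list(
                         list(rounds = 30, max_depth = 2, min_leaf = 40,
                              init_col = 1),
                         list(rounds = 30, max_depth = 3, min_leaf = 40,
                              init_col = 1)),
                       level2 = "lightgbm",
                       level2_params = list(rounds = 30, max_depth = 2,
                                            min_leaf = 40, init_col = 1),
                       level1_input = c("top2", "all"), seed = 1) {
  if (oof_folds < 2) stop("oof_folds must be >= 2")
  reg <- names(learner_registry())
  bad <- setdiff(c(level0, level1, level2), reg)
  if (length(bad)) stop_schema("unknown learner id(s): %s",
                               paste(bad, collapse = ", "))
  structure(list(level0 = level0, level0_params = level0_params,
                 oof_folds = oof_folds, level1 = level1,
                 level1_params = level1_params, level2 = level2,
                 level2_params = level2_params,
                 level1_input = match.arg(level1_input), seed = seed),
            class = "cs_stack_spec")
}

make_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

#' Out-of-fold predictions of one learner
#'
#' Seeded fold assignment; entry i is predicted by the model trained on all
#' folds except fold(i), so no entry is predicted by a model that saw it.
#'
#' @param id Learner id.
#' @param X,y Training data.
#' @param folds Number of folds (n >= folds).
#' @param seed Integer seed (fold assignment and learner fits).
#' @param params Learner overrides.
#' @param fold_id Optional externally fixed fold assignment.
#' @return List `oof` (numeric vector) and `fold_id`.
#' @export
oof_predictions <- function(id, X, y, folds = 10, seed = 1, params = list(),
                            fold_id = NULL) {
  if (!id %in% names(learner_registry()))
    stop_schema("unknown learner id '%s'", id)
  n <- length(y)
  if (n < folds) stop("need n >= folds")
  X <- as_X(X)
  if (is.null(fold_id)) fold_id <- make_folds(n, folds, derive_seed(seed, "split"))
  oof <- numeric(n)
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    m <- fit_learner(id, X[!te, , drop = FALSE], y[!te], params = params,
                     seed = derive_seed(seed, 200L + f))
    oof[te] <- predict(m, X[te, , drop = FALSE])
  }
  list(oof = oof, fold_id = fold_id)
}

rank_learners <- function(r2, rmse, ids) {
  order(-r2, rmse, seq_along(ids))
}

fit_stack_impl <- function(X, y, spec, mode) {
  X <- as_X(X)
  n <- length(y)
  fold_id <- make_folds(n, spec$oof_folds, derive_seed(spec$seed, "split"))
  ids <- spec$level0
  oof <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  full <- vector("list", length(ids)); names(full) <- ids
  for (k in seq_along(ids)) {
    pk <- spec$level0_params[[ids[k]]] %||% list()
    sk <- derive_seed(spec$seed, 300L + k)
    res <- tryCatch(
      oof_predictions(ids[k], X, y, spec$oof_folds, seed = sk, params = pk,
                      fold_id = fold_id),
      error = function(e) stop("base learner '", ids[k], "' failed: ",
                               conditionMessage(e)))
    oof[, k] <- res$oof
    full[[k]] <- fit_learner(ids[k], X, y, params = pk, seed = sk)
  }
  r2 <- apply(oof, 2, r_squared, obs = y)
  rmse <- apply(oof, 2, function(p) sqrt(mean((y - p)^2)))
  ranking <- rank_learners(r2, rmse, ids)
  out <- list(spec = spec, mode = mode, level0 = full, oof = oof,
              fold_id = fold_id, base_r2 = r2, base_rmse = rmse,
              ranking = ids[ranking], feature_names = colnames(X))
  if (mode == "passthrough") {
    # pure concatenation: all OOF columns, ordered by base rank so the
    # final learner's column semantics match the mlsem mode, forwarded
    # without any learnable intermediate transformation
    out$meta_cols <- ids[ranking]
    out$final <- fit_learner(spec$level2, oof[, out$meta_cols, drop = FALSE],
                             y, params = spec$level2_params,
                             seed = derive_seed(spec$seed, 400L))
  } else {
    meta_cols <- if (spec$level1_input == "top2") ids[ranking[1:2]] else ids
    Z <- oof[, meta_cols, drop = FALSE]
    out$meta_cols <- meta_cols
    l1_oof <- matrix(NA_real_, n, length(spec$level1))
    out$level1 <- vector("list", length(spec$level1))
    for (j in seq_along(spec$level1)) {
      pj <- spec$level1_params[[j]] %||% list()
      sj <- derive_seed(spec$seed, 500L + j)
      res <- oof_predictions(spec$level1[j], Z, y, spec$oof_folds, seed = sj,
                             params = pj, fold_id = fold_id)
      l1_oof[, j] <- res$oof
      out$level1[[j]] <- fit_learner(spec$level1[j], Z, y, params = pj,
                                     seed = sj)
    }
    colnames(l1_oof) <- paste0("meta", seq_along(spec$level1))
    out$level1_oof <- l1_oof
    out$final <- fit_learner(spec$level2, l1_oof, y,
                             params = spec$level2_params,
                             seed = derive_seed(spec$seed, 400L))
  }
  structure(out, class = "cs_stack")
}

#' Fit the multi-level stacking ensemble
#'
#' Level-0: the six base learners are trained with `oof_folds`-fold
#' cross-validation and their out-of-fold predictions form the meta-feature
#' matrix; learners are ranked by OOF R^2 (ties: lower OOF RMSE, then
#' registry order). Level-1: two meta-learners are trained — each with its
#' own OOF pass — on the meta-features of the two best base models.
#' Level-2: a final meta-learner is trained on the level-1 OOF outputs.
#'
#' @param X,y Training data (>= 30 rows recommended).
#' @param spec A [stack_spec()].
#' @return Object of class `cs_stack` (mode `"mlsem"`).
#' @export
fit_mlsem <- function(X, y, spec = stack_spec()) {
  stopifnot(inherits(spec, "cs_stack_spec"))
  fit_stack_impl(X, y, spec, "mlsem")
}

#' Fit the pass-through stacking baseline
#'
#' Identical level-0 stage (bit-identical meta-features under the same
#' seed), but the concatenated OOF columns are passed directly — with no
#' learnable intermediate transformation — to the final meta-learner.
#'
#' @inheritParams fit_mlsem
#' @return Object of class `cs_stack` (mode `"passthrough"`).
#' @export
fit_passthrough <- function(X, y, spec = stack_spec()) {
  stopifnot(inherits(spec, "cs_stack_spec"))
  fit_stack_impl(X, y, spec, "passthrough")
}

#' Predict from a fitted stack
#' @param object A `cs_stack`.
#' @param newdata Matrix/data.frame with the training predictor columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.cs_stack <- function(object, newdata, ...) {
  X <- as_X(newdata)
  if (!is.null(colnames(X)) && !identical(colnames(X), object$feature_names)) {
    miss <- setdiff(object$feature_names, colnames(X))
    if (length(miss)) stop_schema("newdata lacks columns: %s",
                                  paste(miss, collapse = ", "))
    X <- X[, object$feature_names, drop = FALSE]
  }
  base <- vapply(object$level0, function(m) predict(m, X), numeric(nrow(X)))
  if (nrow(X) == 1L) base <- matrix(base, nrow = 1,
                                    dimnames = list(NULL, names(object$level0)))
  Z <- base[, object$meta_cols, drop = FALSE]
  if (object$mode == "passthrough") return(predict(object$final, Z))
  l1 <- vapply(object$level1, function(m) predict(m, Z), numeric(nrow(X)))
  if (nrow(X) == 1L) l1 <- matrix(l1, nrow = 1)
  colnames(l1) <- paste0("meta", seq_along(object$level1))
  predict(object$final, l1)
}

#' Regression metrics report
#'
#' R^2 = 1 - SSE/SST, RMSE = sqrt(mean squared error), MAE = mean absolute
#' error. RMSE >= MAE always; R^2 is NA (flagged) for a constant response.
#'
#' @param y,yhat Observed and predicted (equal length >= 2).
#' @return List of class `cs_metrics`: `r2`, `rmse`, `mae`, `n`,
#'   `r2_defined`.
#' @export
evaluate_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  r2 <- r_squared(y, yhat)
  structure(list(r2 = r2, rmse = sqrt(mean((y - yhat)^2)),
                 mae = mean(abs(y - yhat)), n = length(y),
                 r2_defined = !is.na(r2)),
            class = "cs_metrics")
}

#' @export
print.cs_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f, RMSE = %.4f, MAE = %.4f (n = %d)\n",
              x$r2, x$rmse, x$mae, x$n))
  invisible(x)
}

#' Apply a fitted stack to predictor rasters (wall-to-wall map)
#'
#' Predicts every cell where all predictor layers are valid; nodata in any
#' layer propagates to nodata output. The summary reports min/max/mean of
#' the per-hectare predictions over valid cells and the total stock
#' `sum(per-cell volume)` after areal scaling by `cell_size^2 / 10^4`.
#'
#' @param fs A fitted `cs_stack` whose features all appear in `rasters`.
#' @param rasters Named list of [raster_layer()]s on one grid.
#' @return List `map` (per-ha raster), `summary` (min, max, mean, total_m3,
#'   n_valid).
#' @export
apply_map <- function(fs, rasters) {
  need <- fs$feature_names
  miss <- setdiff(need, names(rasters))
  if (length(miss)) stop_schema("missing predictor layer(s): %s",
                                paste(miss, collapse = ", "))
  g <- rasters[[need[1]]]$grid
  X <- vapply(need, function(nm) as.numeric(rasters[[nm]]$values),
              numeric(g$n_rows * g$n_cols))
  colnames(X) <- need
  ok <- complete.cases(X)
  pred <- rep(NA_real_, nrow(X))
  if (any(ok)) pred[ok] <- predict(fs, X[ok, , drop = FALSE])
  map <- raster_layer(g, matrix(pred, g$n_rows))
  v <- pred[ok]
  list(map = map,
       summary = list(min = min(v), max = max(v), mean = mean(v),
                      total_m3 = sum(areal_scale(pmax(v, 0), g$cell_size)),
                      n_valid = sum(ok)))
}

#' Packaged synthetic stacking benchmark
#'
#' One seeded instance of the synthetic world at its documented defaults:
#' spatially autocorrelated canopy fields on a 64x64 30 m grid, track-
#' sampled footprints with measurement noise and quality control, per-metric
#' variogram fits and kriged predictor surfaces, terrain and optical
#' covariates, and `n` plots whose volume is the saturating height-by-cover
#' response plus noise. Predictors reach the models only through the
#' interpolated surfaces, so they carry interpolation and measurement error
#' exactly as in the mapping workflow. On these features the benchmark fits
#' the MLSEM, the pass-through baseline, and every base learner alone on the
#' same 80/20 split, evaluating all of them on the same test rows. Learner
#' sizes are scaled down (documented here: 150 trees/rounds) to keep the
#' 10-seed benchmark inside a desk-scale CPU budget; kriging (not
#' simulation) builds the benchmark surfaces for the same reason.
#'
#' @param n Number of plots drawn (default 500; border plots whose window
#'   features are undefined are dropped, the realized size is reported).
#' @param seed Integer seed.
#' @param noise_sd Plot volume noise sd (m3/ha).
#' @return List with `metrics` (data.frame per model: r2, rmse, mae on
#'   test), `spread` (IQR of test predictions per model), `n_test`, `n`.
#' @export
benchmark_stack <- function(n = 500, seed = 1, noise_sd = 15) {
  sml <- list(n_trees = 150)
  smb <- list(rounds = 150)
  spec <- stack_spec(level0_params = list(rf = sml, xgboost = smb,
                                          gbdt = smb, lightgbm = smb),
                     seed = derive_seed(seed, "stack"))
  dat <- benchmark_world(n, seed, noise_sd)
  nr <- length(dat$y)
  idx <- with_seed(derive_seed(seed, "split"), sample.int(nr, round(0.8 * nr)))
  Xtr <- dat$X[idx, ]; ytr <- dat$y[idx]
  Xte <- dat$X[-idx, ]; yte <- dat$y[-idx]
  models <- list(
    mlsem = fit_mlsem(Xtr, ytr, spec),
    passthrough = fit_passthrough(Xtr, ytr, spec))
  preds <- lapply(models, predict, newdata = Xte)
  for (id in spec$level0) {
    pk <- spec$level0_params[[id]] %||% list()
    m <- fit_learner(id, Xtr, ytr, params = pk,
                     seed = derive_seed(seed, 600L))
    preds[[id]] <- predict(m, Xte)
  }
  metrics <- do.call(rbind, lapply(names(preds), function(nm) {
    mt <- evaluate_metrics(yte, preds[[nm]])
    data.frame(model = nm, r2 = mt$r2, rmse = mt$rmse, mae = mt$mae)
  }))
  spread <- vapply(preds, function(p) diff(quantile(p, c(0.25, 0.75))), 0.0)
  list(metrics = metrics, spread = spread, n_test = length(yte),
       n = length(dat$y))
}

# The benchmark's stated world: the synthetic module at its defaults, with
# predictors delivered through the interpolation stage.
benchmark_world <- function(n, seed, noise_sd = 15) {
  g <- grid_spec(0, cell_size = 30, n_rows = 64, n_cols = 64)
  fields <- list(
    rh98 = simulate_gaussian_field(
      g, vgm_model("exponential", 0.4, 16, 900), 18,
      derive_seed(seed, "field_rh98"), method = "fft"),
    cover = simulate_gaussian_field(
      g, vgm_model("exponential", 0.001, 0.02, 800), 0.55,
      derive_seed(seed, "field_cover"), method = "fft"),
    fhd_normal = simulate_gaussian_field(
      g, vgm_model("spherical", 0.01, 0.16, 700), 2.6,
      derive_seed(seed, "field_fhd"), method = "fft"))
  dem <- simulate_gaussian_field(
    g, vgm_model("spherical", 0, 1600, 1200), 1800,
    derive_seed(seed, "field"), method = "fft")
  fp <- sample_footprints(fields, along_m = 40, across_m = 120,
                          noise_sd = 0.05 *
                            vapply(fields, function(f) sd(f$values), 0.0),
                          qc_fail_frac = 0.12,
                          seed = derive_seed(seed, "footprints"))
  fp <- filter_footprints(fp)
  plots <- simulate_plots(fields, n = n, noise_sd = noise_sd,
                          seed = derive_seed(seed, "plots"))
  surf <- lapply(setNames(names(fields), names(fields)), function(m) {
    ev <- empirical_variogram(fp$x, fp$y, fp[[m]])
    mdl <- fit_variogram(ev)$best$model
    ordinary_kriging(fp$x, fp$y, fp[[m]], g, mdl,
                     max_neighbors = 16)$estimates
  })
  ter <- terrain_attributes(dem)
  nir <- raster_layer(g, 0.18 + 0.22 * pmin(pmax(fields$cover$values, 0), 1))
  rasters <- c(surf, list(slope = ter$slope, elevation = dem,
                          band_nir = nir))
  ft <- suppressWarnings(extract_at_points(rasters, plots))
  list(X = as.matrix(ft[, setdiff(names(ft), "volume_per_ha")]),
       y = ft$volume_per_ha)
}
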