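# Config-driven end-to-end run: QC -> variography -> interpolation + gate ->
# predictor assembly -> VIF + SHAP -> stacking ensemble -> wall-to-wall map.
# Configs are plain lists, serializable as JSON; every threshold lives in
# the config, never in code.

#' Default run configuration (tiny synthetic world)
#'
#' All thresholds default to the study values (sensitivity > 0.9, gate
#' R^2 >= 0.5, VIF 5, top-6, 10 folds, 80/20); the synthetic block describes
#' a desk-scale world (64x64 cells at 30 m) whose footprint density per cell
#' mirrors a real LiDAR track pattern compressed to the small domain.
#'
#' @param seed Global seed; per-stage seeds derive from it.
#' @param n_rows,n_cols Synthetic grid shape.
#' @return Nested config list.
#' @export
default_config <- function(seed = 1, n_rows = 64, n_cols = 64) {
  list(
    seed = seed,
    synthetic = list(
      n_rows = n_rows, n_cols = n_cols, cell_size = 30,
      fields = list(
        rh98  = list(kind = "exponential", nugget = 0.4, psill = 16,
                     range_m = 900, mean = 18),
        cover = list(kind = "exponential", nugget = 0.001, psill = 0.02,
                     range_m = 800, mean = 0.55),
        fhd_normal = list(kind = "spherical", nugget = 0.01, psill = 0.16,
                          range_m = 700, mean = 2.6)),
      footprints = list(along_m = 40, across_m = 120, noise_sd_frac = 0.05,
                        qc_fail_frac = 0.12),
      plots = list(n = 143, noise_sd = 15,
                   coeffs = list(type = "saturating", height_field = "rh98",
                                 cover_field = "cover", vmax = 400, h50 = 12)),
      dem = list(kind = "spherical", nugget = 0, psill = 1600,
                 range_m = 1200, mean = 1800),
      band_noise_sd = 0.01),
    qc = list(sensitivity_min = 0.9, require_quality = TRUE),
    interpolation = list(methods = c("sgcs", "ok", "idw"),
                         surface_method = "sgcs", n_realizations = 10,
                         gate_threshold = 0.5, split_frac = 0.8,
                         max_neighbors = 16),
    selection = list(vif_threshold = 5, top_k = 6,
                     rf_params = list(n_trees = 150)),
    stacking = list(oof_folds = 10, level1_input = "top2",
                    level0_params = list(rf = list(n_trees = 150),
                                         xgboost = list(rounds = 150),
                                         gbdt = list(rounds = 150),
                                         lightgbm = list(rounds = 150)),
                    level2_params = list(rounds = 150),
                    holdout_frac = 0.2, passthrough_baseline = TRUE),
    harmonization = list(dt = 3, cell_size = 30))
}

#' Read / write a config as JSON
#' @param path JSON file path.
#' @param config Config list.
#' @name config_io
#' @export
read_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Synthetic bands: reflectance responds to canopy cover (NIR up, visible
# down) with independent small-scale noise; returned as Collection-2-style
# digital numbers so the pipeline exercises the reflectance scaling.
synth_bands <- function(cover, seed, noise_sd = 0.01) {
  g <- cover$grid
  cv <- pmin(pmax(cover$values, 0), 1)
  base <- list(b1 = 0.020 + 0.005 * (1 - cv), blue = 0.035 + 0.015 * (1 - cv),
               green = 0.06 + 0.02 * (1 - cv), red = 0.05 + 0.05 * (1 - cv),
               nir = 0.18 + 0.22 * cv, swir1 = 0.16 - 0.06 * cv,
               swir2 = 0.09 - 0.04 * cv)
  with_seed(derive_seed(seed, 42L), {
    lapply(base, function(refl) {
      refl <- refl + matrix(rnorm(length(refl), 0, noise_sd), nrow(refl))
      raster_layer(g, round((refl + 0.2) / 0.0000275))
    })
  })
}

stage_msg <- function(name, t0) {
  message(sprintf("[canopystack] %-14s %6.1fs", name,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full pipeline
#'
#' Executes QC, variography, interpolation with the retention gate,
#' predictor assembly, the VIF + SHAP screen, ensemble training and
#' evaluation, and the wall-to-wall map. Reruns with the same config
#' reproduce the report exactly (timings are logged to stderr, not stored).
#'
#' @param config A config list (see [default_config()]); either a
#'   `synthetic` block or `paths` (footprints/plots CSV, raster dir).
#' @param out_dir Optional directory for artifacts (report.json, map.asc,
#'   tables).
#' @return RunReport list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  t0 <- proc.time()[3]
  seed <- config$seed %||% 1
  report <- list(config = config, package_version =
                   as.character(utils::packageVersion("canopystack")))

  # ---- inputs: synthetic world or files -------------------------------
  if (!is.null(config$synthetic)) {
    sb <- config$synthetic
    grid <- grid_spec(0, cell_size = sb$cell_size, n_rows = sb$n_rows,
                      n_cols = sb$n_cols)
    fields <- list()
    for (nm in names(sb$fields)) {
      fd <- sb$fields[[nm]]
      fields[[nm]] <- simulate_gaussian_field(
        grid, vgm_model(fd$kind, fd$nugget, fd$psill, fd$range_m),
        mean = fd$mean, seed = derive_seed(seed, paste0("field_", nm)))
    }
    dem <- simulate_gaussian_field(
      grid, vgm_model(sb$dem$kind, sb$dem$nugget, sb$dem$psill,
                      sb$dem$range_m),
      mean = sb$dem$mean, seed = derive_seed(seed, "field"))
    # measurement noise scales with each field's own spatial variability
    noise <- vapply(fields, function(f) sd(f$values), 0.0) *
      sb$footprints$noise_sd_frac
    fp <- sample_footprints(fields, along_m = sb$footprints$along_m,
                            across_m = sb$footprints$across_m,
                            noise_sd = noise,
                            qc_fail_frac = sb$footprints$qc_fail_frac,
                            seed = derive_seed(seed, "footprints"))
    plots <- simulate_plots(fields, n = sb$plots$n,
                            coeffs = sb$plots$coeffs,
                            noise_sd = sb$plots$noise_sd,
                            seed = derive_seed(seed, "plots"))
    bands_dn <- synth_bands(fields$cover %||% fields[[1]], seed,
                            sb$band_noise_sd %||% 0.01)
  } else {
    p <- config$paths
    if (is.null(p$footprints) || !file.exists(p$footprints))
      stop("pipeline aborted at stage 'inputs': footprint path missing")
    if (is.null(p$plots) || !file.exists(p$plots))
      stop("pipeline aborted at stage 'inputs': plots path missing")
    fp <- read_table_csv(p$footprints)
    plots <- read_table_csv(p$plots)
    dem <- read_ascii_grid(p$dem)
    grid <- dem$grid
    bands_dn <- lapply(p$bands, read_ascii_grid)
  }
  stage_msg("inputs", t0)

  # ---- QC --------------------------------------------------------------
  fp_qc <- filter_footprints(fp, config$qc$sensitivity_min,
                             config$qc$require_quality)
  report$qc <- list(n_raw = nrow(fp), n_retained = nrow(fp_qc))
  metrics <- setdiff(names(fp_qc), c("id", "x", "y", "sensitivity",
                                     "quality_flag"))
  stage_msg("qc", t0)

  # ---- variography -----------------------------------------------------
  report$variograms <- lapply(setNames(metrics, metrics), function(m) {
    ev <- empirical_variogram(fp_qc$x, fp_qc$y, fp_qc[[m]])
    fit <- fit_variogram(ev)$best
    list(kind = fit$model$kind, nugget = fit$model$nugget,
         psill = fit$model$psill, range_m = fit$model$range_m,
         r2 = fit$r2, rss = fit$rss,
         structural_ratio = fit$model$structural_ratio,
         category = classify_spatial_dependence(fit$model))
  })
  stage_msg("variography", t0)

  # ---- interpolation + gate -------------------------------------------
  ic <- config$interpolation
  models <- lapply(setNames(metrics, metrics), function(m)
    vgm_model(report$variograms[[m]]$kind, report$variograms[[m]]$nugget,
              report$variograms[[m]]$psill, report$variograms[[m]]$range_m))
  report$interpolation <- list()
  surfaces <- list()
  for (m in metrics) {
    reps <- lapply(ic$methods, function(meth)
      evaluate_interpolation(fp_qc, m, meth, grid = grid,
                             model = models[[m]],
                             split_frac = ic$split_frac,
                             threshold = ic$gate_threshold,
                             seed = derive_seed(seed, "interpolate"),
                             n_realizations = ic$n_realizations,
                             max_neighbors = ic$max_neighbors))
    names(reps) <- ic$methods
    report$interpolation[[m]] <- lapply(reps, unclass)
    gate_rep <- reps[[ic$surface_method]]
    if (gate_rep$retained) {
      surfaces[[m]] <- switch(ic$surface_method,
        "sgcs" = realization_mean(
          sgcs(fp_qc$x, fp_qc$y, fp_qc[[m]], grid, models[[m]],
               n_realizations = ic$n_realizations,
               seed = derive_seed(seed, "interpolate"),
               max_neighbors = min(ic$max_neighbors, 16))),
        "ok" = ordinary_kriging(fp_qc$x, fp_qc$y, fp_qc[[m]], grid,
                                models[[m]],
                                max_neighbors = ic$max_neighbors)$estimates,
        idw(fp_qc$x, fp_qc$y, fp_qc[[m]], grid, beta = 2))
    }
  }
  report$retained_metrics <- names(surfaces)
  stage_msg("interpolation", t0)

  # ---- harmonization ---------------------------------------------------
  hc <- config$harmonization
  plots_h <- harmonize_plots(plots, dt = hc$dt, cell_size = hc$cell_size)
  report$harmonization <- list(dt = hc$dt, cell_size = hc$cell_size,
                               mean_projected = mean(plots_h$volume_projected))
  stage_msg("harmonization", t0)

  # ---- predictor assembly + selection ---------------------------------
  bands <- lapply(bands_dn, function(b)
    raster_layer(b$grid, scale_reflectance(b$values)))
  candidates <- assemble_candidates(surfaces, dem, bands)
  report$n_candidates <- length(candidates)
  ftab <- extract_at_points(candidates, plots_h, response = "volume_projected")
  sel <- vif_select(ftab, threshold = config$selection$vif_threshold,
                    response = "volume_projected")
  sel <- shap_rank(ftab, sel, top_k = config$selection$top_k,
                   seed = derive_seed(seed, "select"),
                   response = "volume_projected",
                   rf_params = config$selection$rf_params %||% list())
  report$selection <- list(vif_trace = sel$vif_trace,
                           retained_after_vif = sel$retained_after_vif,
                           shap_ranking = sel$shap_ranking,
                           final_features = sel$final_features)
  stage_msg("selection", t0)

  # ---- stacking --------------------------------------------------------
  sc <- config$stacking
  spec <- stack_spec(oof_folds = sc$oof_folds,
                     level0_params = sc$level0_params %||% list(),
                     level2_params = sc$level2_params %||% list(),
                     level1_input = sc$level1_input %||% "top2",
                     seed = derive_seed(seed, "stack"))
  X <- as.matrix(ftab[, sel$final_features, drop = FALSE])
  y <- ftab$volume_projected
  n <- length(y)
  idx <- with_seed(derive_seed(seed, "split"),
                   sample.int(n, round((1 - (sc$holdout_frac %||% 0.2)) * n)))
  fs <- fit_mlsem(X[idx, , drop = FALSE], y[idx], spec)
  pred_te <- predict(fs, X[-idx, , drop = FALSE])
  report$stacking <- list(
    base_oof_r2 = as.list(fs$base_r2), ranking = fs$ranking,
    holdout = unclass(evaluate_metrics(y[-idx], pred_te)))
  if (isTRUE(sc$passthrough_baseline)) {
    ps <- fit_passthrough(X[idx, , drop = FALSE], y[idx], spec)
    report$stacking$passthrough_holdout <-
      unclass(evaluate_metrics(y[-idx], predict(ps, X[-idx, , drop = FALSE])))
  }
  stage_msg("stacking", t0)

  # ---- wall-to-wall map ------------------------------------------------
  mp <- apply_map(fs, candidates[sel$final_features])
  report$map_summary <- mp$summary
  stage_msg("map", t0)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ascii_grid(mp$map, file.path(out_dir, "fsv_map.asc"))
    write_table_csv(plots_h, file.path(out_dir, "plots_harmonized.csv"))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  report
}
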