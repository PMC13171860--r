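# Optical, texture and terrain predictors, plot-level feature assembly, and
# the two-stage collinearity (VIF) + importance (SHAP) screen.

#' Scale optical digital numbers to surface reflectance
#'
#' Collection-2 Level-2 convention: reflectance = 0.0000275 * DN - 0.2.
#' @param dn Digital numbers (any shape; rasters pass their values matrix).
#' @return Reflectance, same shape.
#' @export
scale_reflectance <- function(dn) 0.0000275 * dn - 0.2

#' Vegetation indices from reflectance bands
#'
#' Computes the 11 standard indices NDVI, DVI, RVI, EVI, SAVI, ARVI, TVI,
#' RDVI, VDVI, NGBDI, NPCI from named reflectance rasters. Formulas are the
#' published standards: EVI uses G = 2.5, C1 = 6, C2 = 7.5, L = 1; SAVI uses
#' soil factor L = 0.5; TVI is the triangular index
#' 0.5 * (120 (NIR - G) - 200 (R - G)). Division by zero yields nodata.
#'
#' @param bands Named list of [raster_layer()]s with at least `blue`,
#'   `green`, `red`, `nir`.
#' @return Named list of 11 index rasters.
#' @export
vegetation_indices <- function(bands) {
  need <- c("blue", "green", "red", "nir")
  miss <- setdiff(need, names(bands))
  if (length(miss)) stop_schema("missing band(s): %s", paste(miss, collapse = ", "))
  g <- bands$blue$grid
  B <- bands$blue$values; G <- bands$green$values
  R <- bands$red$values;  N <- bands$nir$values
  sdiv <- function(num, den) {
    out <- num / den
    out[!is.finite(out)] <- NA_real_
    out
  }
  idx <- list(
    NDVI  = sdiv(N - R, N + R),
    DVI   = N - R,
    RVI   = sdiv(N, R),
    EVI   = sdiv(2.5 * (N - R), N + 6 * R - 7.5 * B + 1),
    SAVI  = sdiv(1.5 * (N - R), N + R + 0.5),
    ARVI  = sdiv(N - (2 * R - B), N + (2 * R - B)),
    TVI   = 0.5 * (120 * (N - G) - 200 * (R - G)),
    RDVI  = sdiv(N - R, sqrt(pmax(N + R, 0))),
    VDVI  = sdiv(2 * G - R - B, 2 * G + R + B),
    NGBDI = sdiv(G - B, G + B),
    NPCI  = sdiv(R - B, R + B))
  lapply(idx, raster_layer, grid = g)
}

# GLCM features of one normalized symmetric co-occurrence matrix given as
# pair probabilities (i, j, p) with i, j 1-based gray levels.
glcm_features_from_pairs <- function(i, j, p) {
  mu <- sum(i * p)                      # symmetric: row marginal == col
  s2 <- sum((i - mu)^2 * p)
  ent <- -sum(p * log(p))
  corr <- if (s2 > 0) sum((i - mu) * (j - mu) * p) / s2 else 1
  c(glcm_mean = mu, glcm_variance = s2,
    glcm_homogeneity = sum(p / (1 + (i - j)^2)),
    glcm_contrast = sum(p * (i - j)^2),
    glcm_dissimilarity = sum(p * abs(i - j)),
    glcm_entropy = ent, glcm_asm = sum(p^2), glcm_correlation = corr)
}

#' Gray-level co-occurrence texture features
#'
#' Per-cell GLCM over a sliding window: the band is linearly quantized to
#' `levels` gray levels over its valid range, and for each window a
#' symmetric, normalized co-occurrence matrix is accumulated over the four
#' orientations (0, 45, 90, 135 degrees) at the given displacement. Eight
#' Haralick-type features are returned: mean, variance, homogeneity,
#' contrast, dissimilarity, entropy, angular second moment, correlation
#' (correlation of a zero-variance window is 1 by convention). Border cells
#' (window incomplete) are nodata.
#'
#' @param band A [raster_layer()].
#' @param window Odd window edge length (default 5).
#' @param levels Quantization levels (default 64).
#' @param displacement Co-occurrence offset in pixels (default 1).
#' @return Named list of 8 feature rasters.
#' @export
glcm_textures <- function(band, window = 5, levels = 64, displacement = 1) {
  stopifnot(window %% 2 == 1, levels >= 2, displacement >= 1)
  v <- band$values
  nr <- nrow(v); nc <- ncol(v)
  if (window > nr || window > nc) stop("window larger than raster")
  rng <- range(v, na.rm = TRUE)
  q <- if (diff(rng) > 0)
    pmin(floor((v - rng[1]) / diff(rng) * levels) + 1L, levels)
  else matrix(1L, nr, nc)
  half <- (window - 1) %/% 2
  feats <- c("glcm_mean", "glcm_variance", "glcm_homogeneity",
             "glcm_contrast", "glcm_dissimilarity", "glcm_entropy",
             "glcm_asm", "glcm_correlation")
  out <- lapply(feats, function(f) matrix(NA_real_, nr, nc))
  names(out) <- feats
  d <- displacement
  offs <- list(c(0, d), c(d, 0), c(d, d), c(d, -d))  # E, S, SE, SW
  for (r in (half + 1):(nr - half)) {
    for (cc in (half + 1):(nc - half)) {
      w <- q[(r - half):(r + half), (cc - half):(cc + half)]
      if (anyNA(w)) next
      ii <- integer(0); jj <- integer(0)
      for (o in offs) {
        rows <- seq_len(window - abs(o[1]))
        cols <- if (o[2] >= 0) seq_len(window - o[2]) else (1 - o[2]):window
        a <- w[rows, cols, drop = FALSE]
        b <- w[rows + abs(o[1]), cols + o[2], drop = FALSE]
        ii <- c(ii, a, b); jj <- c(jj, b, a)   # symmetric accumulation
      }
      code <- (ii - 1L) * levels + jj
      tab <- table(code)
      p <- as.numeric(tab) / length(code)
      codes <- as.integer(names(tab))
      fi <- (codes - 1L) %/% levels + 1L
      fj <- (codes - 1L) %% levels + 1L
      vals <- glcm_features_from_pairs(fi, fj, p)
      for (f in feats) out[[f]][r, cc] <- vals[[f]]
    }
  }
  lapply(out, raster_layer, grid = band$grid)
}

#' Terrain derivatives from a DEM
#'
#' Horn 3x3 finite differences. Slope in degrees `[0, 90)`; aspect in
#' degrees clockwise from north (direction of steepest descent), with flat
#' cells given the sentinel -1. Border cells are nodata.
#'
#' @param dem A [raster_layer()] of elevations (m).
#' @param flat_tol Gradient magnitude below which a cell counts as flat.
#' @return List with `slope` and `aspect` rasters.
#' @export
terrain_attributes <- function(dem, flat_tol = 1e-10) {
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) stop("raster smaller than 3x3")
  cs <- dem$grid$cell_size
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  a <- v[ri - 1, ci - 1]; b <- v[ri - 1, ci]; cc_ <- v[ri - 1, ci + 1]
  d <- v[ri, ci - 1];                         f <- v[ri, ci + 1]
  g <- v[ri + 1, ci - 1]; h <- v[ri + 1, ci]; i <- v[ri + 1, ci + 1]
  gx <- ((cc_ + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)     # +x east
  gy <- ((a + 2 * b + cc_) - (g + 2 * h + i)) / (8 * cs)     # +y north
  slope_i <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  asp_i <- (atan2(-gx, -gy) * 180 / pi) %% 360
  asp_i[sqrt(gx^2 + gy^2) < flat_tol] <- -1
  slope <- aspect <- matrix(NA_real_, nr, nc)
  slope[ri, ci] <- slope_i
  aspect[ri, ci] <- asp_i
  list(slope = raster_layer(dem$grid, slope),
       aspect = raster_layer(dem$grid, aspect))
}

#' Extract raster values at plot locations into a feature table
#'
#' Cell-center nearest lookup per raster; plots outside the shared extent
#' (or hitting nodata in any layer) are dropped with a warning.
#'
#' @param rasters Named list of [raster_layer()]s on one grid.
#' @param plots Plot table with `x`, `y` and `volume_per_ha`.
#' @param response Response column copied into the table (default
#'   `volume_per_ha`).
#' @return data.frame: one row per surviving plot, predictor columns named
#'   as `rasters`, plus the response column.
#' @export
extract_at_points <- function(rasters, plots, response = "volume_per_ha") {
  g <- rasters[[1]]$grid
  for (r in rasters) if (!same_grid(r$grid, g))
    stop_schema("all rasters must share one grid")
  ft <- data.frame(row.names = seq_len(nrow(plots)))
  for (nm in names(rasters)) ft[[nm]] <- raster_at(rasters[[nm]], plots$x, plots$y)
  if (response %in% names(plots)) ft[[response]] <- plots[[response]]
  keep <- complete.cases(ft)
  if (!all(keep))
    warning(sum(!keep), " plot(s) outside extent or on nodata; dropped")
  ft <- ft[keep, , drop = FALSE]
  if (nrow(ft) == 0) stop("no plots survive extraction")
  ft
}

vif_values <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(i) {
    yi <- X[, i]
    if (sd(yi) == 0) return(Inf)
    others <- X[, -i, drop = FALSE]
    fit <- tryCatch(lm.fit(cbind(1, others), yi), error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / sum((yi - mean(yi))^2)
    if (r2 >= 1 - 1e-12) Inf else min(1 / (1 - r2), 1e6)
  }, 0.0)
}

#' Stepwise VIF-based collinearity screen
#'
#' Iteratively removes the predictor with the largest variance inflation
#' factor while any VIF exceeds `threshold`, recomputing VIFs after each
#' removal. VIF_i = 1/(1 - R_i^2) from regressing predictor i on the rest;
#' constant or perfectly collinear columns get an infinite VIF and are
#' removed first. When rows <= predictors the least-squares fit is rank
#' deficient and the capped pseudo-inverse R^2 is used (VIF capped at 1e6).
#'
#' @param ft Feature table (data.frame); `response` column is excluded from
#'   the screen.
#' @param threshold VIF threshold (default 5, strict: retained VIFs are all
#'   < threshold on exit).
#' @param response Response column name.
#' @return List of class `cs_selection`: `retained_after_vif`, `vif_trace`
#'   (removed name + VIF at removal), `vif_final` (named VIFs of retained).
#' @export
vif_select <- function(ft, threshold = 5, response = "volume_per_ha") {
  X <- as.matrix(ft[, setdiff(names(ft), response), drop = FALSE])
  if (ncol(X) < 2) stop("need >= 2 predictors")
  trace <- data.frame(removed = character(0), vif = numeric(0))
  repeat {
    v <- vif_values(X)
    if (ncol(X) <= 1 || max(v) <= threshold) break
    worst <- which.max(v)
    trace <- rbind(trace, data.frame(removed = colnames(X)[worst],
                                     vif = v[worst]))
    X <- X[, -worst, drop = FALSE]
  }
  structure(list(retained_after_vif = colnames(X), vif_trace = trace,
                 vif_final = setNames(vif_values(X), colnames(X)),
                 threshold = threshold),
            class = "cs_selection")
}

#' SHAP-based importance ranking and top-k selection
#'
#' Fits a random-forest regressor (fixed seed) on the post-VIF predictors
#' and ranks them by mean absolute exact tree-path SHAP value over the
#' training rows; the top `top_k` form the final feature set.
#'
#' @param ft Feature table.
#' @param selection A [vif_select()] result (or NULL to use all predictors).
#' @param top_k Number of features to retain (default 6).
#' @param seed Integer seed.
#' @param response Response column name.
#' @param rf_params Random-forest overrides (e.g. smaller `n_trees` in
#'   tests).
#' @return The `cs_selection` extended with `shap_ranking` (data.frame name,
#'   mean_abs_shap, sorted) and `final_features`.
#' @export
shap_rank <- function(ft, selection = NULL, top_k = 6, seed = 1,
                      response = "volume_per_ha", rf_params = list()) {
  keep <- if (is.null(selection)) setdiff(names(ft), response)
          else selection$retained_after_vif
  X <- ft[, keep, drop = FALSE]
  y <- ft[[response]]
  model <- fit_learner("rf", X, y, params = rf_params, seed = seed)
  sv <- shap_values(model, X)
  imp <- colMeans(abs(sv$shap))
  ord <- order(-imp)
  ranking <- data.frame(name = keep[ord], mean_abs_shap = imp[ord],
                        row.names = NULL)
  if (top_k > length(keep)) {
    warning("top_k exceeds retained predictors; returning all")
    top_k <- length(keep)
  }
  out <- selection %||% structure(list(retained_after_vif = keep),
                                  class = "cs_selection")
  out$shap_ranking <- ranking
  out$final_features <- ranking$name[seq_len(top_k)]
  out$shap_model_seed <- seed
  out
}

#' Assemble the multi-source candidate predictor stack
#'
#' Combines gated LiDAR-metric surfaces, terrain derivatives (slope, aspect,
#' elevation), single-band reflectances, vegetation indices, and textures
#' into one named raster list; with the study configuration (6 gated
#' surfaces + 3 terrain + 7 bands + 11 indices + 8 textures) this yields 35
#' candidate predictors.
#'
#' @param gedi_surfaces Named list of gated interpolated metric rasters.
#' @param dem Elevation raster.
#' @param bands Named list of reflectance band rasters (those named here
#'   enter as single-band predictors; must include blue/green/red/nir for
#'   the indices).
#' @param texture_band Name in `bands` used for GLCM textures (default
#'   `"nir"`).
#' @param glcm_window,glcm_levels GLCM settings.
#' @return Named list of rasters (the candidate FeatureTable columns).
#' @export
assemble_candidates <- function(gedi_surfaces, dem, bands,
                                texture_band = "nir", glcm_window = 5,
                                glcm_levels = 64) {
  ter <- terrain_attributes(dem)
  out <- c(gedi_surfaces,
           list(slope = ter$slope, aspect = ter$aspect, elevation = dem),
           setNames(bands, paste0("band_", names(bands))),
           vegetation_indices(bands),
           glcm_textures(bands[[texture_band]], window = glcm_window,
                         levels = glcm_levels))
  if (anyDuplicated(names(out))) stop_schema("duplicate predictor names")
  out
}
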