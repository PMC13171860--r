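test_that("reflectance scaling is the printed affine map", {
  expect_equal(scale_reflectance(0), -0.2)
  expect_equal(scale_reflectance(20000), 0.35)
  a <- 12345; b <- 6789
  expect_equal(scale_reflectance(a) + scale_reflectance(b) -
                 scale_reflectance(0), scale_reflectance(a + b))
})

make_bands <- function(n = 8, seed = 1) {
  g <- tiny_grid(n)
  withr::with_seed(seed, {
    mk <- function(lo, hi) raster_layer(g, matrix(runif(n * n, lo, hi), n))
    list(blue = mk(0.02, 0.08), green = mk(0.04, 0.1),
         red = mk(0.03, 0.12), nir = mk(0.15, 0.45))
  })
}

test_that("vegetation indices: closed forms, bounds, schema", {
  b <- make_bands()
  idx <- vegetation_indices(b)
  expect_setequal(names(idx), c("NDVI", "DVI", "RVI", "EVI", "SAVI", "ARVI",
                                "TVI", "RDVI", "VDVI", "NGBDI", "NPCI"))
  N <- b$nir$values; R <- b$red$values; G <- b$green$values; B <- b$blue$values
  expect_equal(idx$NDVI$values, (N - R) / (N + R))
  expect_equal(idx$DVI$values, N - R)
  expect_equal(idx$SAVI$values, 1.5 * (N - R) / (N + R + 0.5))
  expect_equal(idx$EVI$values, 2.5 * (N - R) / (N + 6 * R - 7.5 * B + 1))
  expect_equal(idx$TVI$values, 0.5 * (120 * (N - G) - 200 * (R - G)))
  # NIR == red makes NDVI zero
  b2 <- b; b2$nir <- b$red
  expect_true(all(vegetation_indices(b2)$NDVI$values == 0))
  # spot value: (0.4 - 0.2) / (0.4 + 0.2)
  g1 <- grid_spec(0, 30, 30, 1, 1)
  one <- function(v) raster_layer(g1, v)
  nd <- vegetation_indices(list(blue = one(0.05), green = one(0.1),
                                red = one(0.2), nir = one(0.4)))$NDVI
  expect_equal(nd$values[1, 1], 1 / 3, tolerance = 1e-12)
  # normalized-difference indices bounded on valid reflectance
  for (nm in c("NDVI", "VDVI", "NGBDI"))
    expect_true(all(abs(idx[[nm]]$values) <= 1))
  expect_error(vegetation_indices(b[c("blue", "red", "nir")]), "green")
})

test_that("GLCM: constant window, oracle patch, orientation symmetry", {
  g <- tiny_grid(7)
  flat <- raster_layer(g, 5)
  tx <- glcm_textures(flat, window = 5, levels = 8)
  ctr <- function(r) r$values[4, 4]
  expect_equal(ctr(tx$glcm_contrast), 0)
  expect_equal(ctr(tx$glcm_dissimilarity), 0)
  expect_equal(ctr(tx$glcm_homogeneity), 1)
  expect_equal(ctr(tx$glcm_entropy), 0)
  expect_equal(ctr(tx$glcm_asm), 1)
  expect_equal(ctr(tx$glcm_correlation), 1)
  expect_true(is.na(tx$glcm_mean$values[1, 1]))     # border is nodata

  # printed 5x5 patch with 2 gray levels vs the hand-tabulation oracle
  patch <- matrix(c(0, 0, 1, 1, 0,
                    0, 1, 1, 0, 0,
                    1, 1, 0, 0, 1,
                    0, 0, 1, 1, 1,
                    1, 0, 0, 1, 0), 5, 5, byrow = TRUE)
  rp <- raster_layer(grid_spec(0, 150, 30, 5, 5), patch)
  got <- glcm_textures(rp, window = 5, levels = 2)
  q <- patch + 1L   # the linear quantizer maps {0,1} to levels {1,2}
  want <- oracle_glcm_center(q, levels = 2)
  for (nm in names(want))
    expect_equal(got[[nm]]$values[3, 3], unname(want[nm]), tolerance = 1e-12)
  # reversing the displacement direction leaves features unchanged
  want_rev <- oracle_glcm_center(q, levels = 2, negate = TRUE)
  expect_equal(want, want_rev, tolerance = 1e-12)

  expect_error(glcm_textures(flat, window = 4), "window")
  expect_error(glcm_textures(flat, window = 9), "larger")
})

test_that("terrain: flat, analytic plane, hand Horn kernel", {
  g <- tiny_grid(6, cell = 30)
  ter0 <- terrain_attributes(raster_layer(g, 100))
  inner <- ter0$slope$values[2:5, 2:5]
  expect_true(all(inner == 0))
  expect_true(all(ter0$aspect$values[2:5, 2:5] == -1))

  # plane z = 0.1 x: slope atan(0.1), west-facing (270 deg)
  rc <- expand.grid(row = 1:6, col = 1:6)
  cc <- cell_centers(g, rc$row, rc$col)
  plane <- raster_layer(g, matrix(0.1 * cc$x, 6, 6))
  tp <- terrain_attributes(plane)
  expect_equal(tp$slope$values[3, 3], atan(0.1) * 180 / pi, tolerance = 1e-9)
  expect_equal(tp$aspect$values[3, 3], 270)

  # hand-computed Horn gradient on an irregular 3x3 patch
  z <- matrix(c(10, 12, 13,
                9, 11, 14,
                8, 10, 12), 3, 3, byrow = TRUE)
  t3 <- terrain_attributes(raster_layer(grid_spec(0, 90, 30, 3, 3), z))
  gx <- ((13 + 2 * 14 + 12) - (10 + 2 * 9 + 8)) / (8 * 30)
  gy <- ((10 + 2 * 12 + 13) - (8 + 2 * 10 + 12)) / (8 * 30)
  expect_equal(t3$slope$values[2, 2], atan(sqrt(gx^2 + gy^2)) * 180 / pi)
  expect_equal(t3$aspect$values[2, 2], (atan2(-gx, -gy) * 180 / pi) %% 360)
  expect_error(terrain_attributes(raster_layer(grid_spec(0, 60, 30, 2, 2),
                                               1)), "3x3")
})

test_that("point extraction matches brute-force lookup and drops outsiders", {
  f1 <- tiny_field(10, seed = 1); f2 <- tiny_field(10, seed = 2)
  g <- f1$grid
  pts <- withr::with_seed(5, data.frame(
    x = runif(12, 0, 300), y = runif(12, 0, 300),
    volume_per_ha = runif(12, 10, 200)))
  ft <- extract_at_points(list(a = f1, b = f2), pts)
  for (i in seq_len(nrow(pts))) {
    ridx <- floor((300 - pts$y[i]) / 30) + 1
    cidx <- floor(pts$x[i] / 30) + 1
    expect_equal(ft$a[i], f1$values[ridx, cidx])
    expect_equal(ft$b[i], f2$values[ridx, cidx])
  }
  # exact value at a cell center
  cc <- cell_centers(g, 4, 7)
  ft2 <- extract_at_points(list(a = f1),
                           data.frame(x = cc$x, y = cc$y, volume_per_ha = 1))
  expect_equal(ft2$a, f1$values[4, 7])
  # outside point dropped with a warning
  pts$x[3] <- 1e6
  expect_warning(ft3 <- extract_at_points(list(a = f1, b = f2), pts),
                 "dropped")
  expect_equal(nrow(ft3), 11)
  expect_error(suppressWarnings(extract_at_points(
    list(a = f1), data.frame(x = -10, y = -10, volume_per_ha = 1))),
    "no plots")
})

test_that("VIF screen: identities, duplicates, regression oracle", {
  n <- 200
  # orthogonal design: all VIF = 1, nothing removed
  Xo <- withr::with_seed(1, qr.Q(qr(matrix(rnorm(n * 4), n))))
  fto <- as.data.frame(Xo); names(fto) <- paste0("o", 1:4)
  fto$volume_per_ha <- withr::with_seed(2, rnorm(n))
  so <- vif_select(fto)
  expect_setequal(so$retained_after_vif, paste0("o", 1:4))
  # columns are mutually orthogonal but not orthogonal to the intercept,
  # so the VIFs sit within sampling noise of 1
  expect_true(all(abs(so$vif_final - 1) < 0.05))
  expect_equal(nrow(so$vif_trace), 0)

  # duplicated column: one copy removed on the first iteration
  ftd <- fto; ftd$dup <- ftd$o1
  sd1 <- vif_select(ftd)
  expect_equal(nrow(sd1$vif_trace), 1)
  expect_true(sd1$vif_trace$removed[1] %in% c("o1", "dup"))
  expect_true(all(sd1$vif_final < 5))

  # correlated predictors: VIF matches per-column lm 1/(1-R2)
  X <- withr::with_seed(3, {
    z <- rnorm(n)
    cbind(p1 = z + rnorm(n, 0, 0.5), p2 = z + rnorm(n, 0, 0.7),
          p3 = rnorm(n))
  })
  want <- vapply(1:3, function(i) {
    r2 <- summary(lm(X[, i] ~ X[, -i]))$r.squared
    1 / (1 - r2)
  }, 0.0)
  got <- canopystack:::vif_values(X)
  expect_equal(got, want, tolerance = 1e-8)

  expect_error(vif_select(fto["volume_per_ha"]), "2 predictors")
})

test_that("stepwise VIF always exits below the threshold", {
  n <- 120
  X <- withr::with_seed(9, {
    z1 <- rnorm(n); z2 <- rnorm(n)
    data.frame(a = z1, b = z1 + rnorm(n, 0, 0.1), c = z1 + rnorm(n, 0, 0.2),
               d = z2, e = z2 + rnorm(n, 0, 0.15), f = rnorm(n))
  })
  X$volume_per_ha <- withr::with_seed(10, rnorm(n))
  s <- vif_select(X, threshold = 5)
  expect_true(all(s$vif_final < 5))
  expect_gt(nrow(s$vif_trace), 0)
  expect_true(all(s$vif_trace$vif > 5))
})

test_that("SHAP ranking: determinism, inert features, top-k", {
  d <- toy_xy(150, seed = 4)
  ft <- as.data.frame(d$X)
  ft$inert <- 1                      # constant: never used in a split
  ft$volume_per_ha <- d$y
  rnk <- shap_rank(ft, top_k = 3, seed = 11, rf_params = list(n_trees = 60))
  rnk2 <- shap_rank(ft, top_k = 3, seed = 11, rf_params = list(n_trees = 60))
  expect_identical(rnk$shap_ranking, rnk2$shap_ranking)
  expect_equal(rnk$shap_ranking$mean_abs_shap[
    rnk$shap_ranking$name == "inert"], 0)
  expect_identical(tail(rnk$shap_ranking$name, 1), "inert")
  expect_length(rnk$final_features, 3)
  expect_true(all(rnk$final_features %in% rnk$retained_after_vif))
  expect_warning(rbig <- shap_rank(ft, top_k = 99, seed = 1,
                                   rf_params = list(n_trees = 20)), "top_k")
  expect_length(rbig$final_features, 5)
})

test_that("candidate assembly produces uniquely named layers", {
  n <- 9
  b <- make_bands(n, seed = 2)
  b$b1 <- b$blue; b$swir1 <- b$green; b$swir2 <- b$red   # 7 named bands
  dem <- tiny_field(n, seed = 3, psill = 900, range_m = 600, mean = 1500)
  surf <- list(s1 = tiny_field(n, seed = 4), s2 = tiny_field(n, seed = 5))
  cand <- assemble_candidates(surf, dem, b, glcm_levels = 16)
  expect_equal(length(cand), 2 + 3 + 7 + 11 + 8)
  expect_false(anyDuplicated(names(cand)) > 0)
  expect_true(all(c("slope", "aspect", "elevation", "band_nir", "NDVI",
                    "glcm_entropy") %in% names(cand)))
})
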