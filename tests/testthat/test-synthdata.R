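test_that("field simulator: degenerate, deterministic, and rejects bad input", {
  g <- tiny_grid(8)
  # zero-variance model gives a constant field equal to the mean
  r0 <- simulate_gaussian_field(g, vgm_model("spherical", 0, 0, 100), 5, 1)
  expect_true(all(r0$values == 5))
  # same seed twice: bit-identical
  a <- tiny_field(12, seed = 9)
  b <- tiny_field(12, seed = 9)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, tiny_field(12, seed = 10)$values))
  expect_error(vgm_model("spherical", psill = -1), "sill")
  expect_error(vgm_model("spherical", range_m = 0), "range")
  expect_identical(attr(a, "sim_method"), "chol")
})

test_that("field simulator reproduces the model variogram (seed-averaged)", {
  g <- tiny_grid(24)
  mdl <- vgm_model("spherical", 0, 1, 300)
  rc <- expand.grid(row = 1:24, col = 1:24)
  cc <- cell_centers(g, rc$row, rc$col)
  acc <- NULL
  for (s in 1:20) {
    r <- simulate_gaussian_field(g, mdl, 0, seed = s)
    ev <- empirical_variogram(cc$x, cc$y, as.numeric(r$values),
                              lag_width = 30, max_lag = 270)
    acc <- rbind(acc, ev$semivariances)
  }
  emp <- colMeans(acc)
  # evaluate the model at the pair-weighted mean distance of each bin
  # (pairs sit on discrete grid distances, so bin midpoints are biased)
  mod <- semivariance(mdl, ev$lag_means)
  # lags below the range: mean over 20 seeds within 15% of the model
  expect_lt(max(abs(emp - mod) / mod), 0.15)
})

test_that("ensemble variance at a cell approaches the sill", {
  g <- tiny_grid(6)
  mdl <- vgm_model("exponential", 0.2, 0.8, 200)
  vals <- vapply(1:60, function(s)
    simulate_gaussian_field(g, mdl, 3, seed = s)$values[3, 4], 0.0)
  # sill = 1; 60-seed variance estimate has sd ~ sqrt(2/59) ~ 0.18
  expect_lt(abs(var(vals) - mdl$sill), 3 * sqrt(2 / 59) * mdl$sill)
})

test_that("fft circulant-embedding path matches the target marginally", {
  g <- grid_spec(0, cell_size = 30, n_rows = 70, n_cols = 70)
  mdl <- vgm_model("exponential", 0, 2, 300)
  r <- simulate_gaussian_field(g, mdl, 1, seed = 4, method = "fft")
  expect_identical(attr(r, "sim_method"), "fft")
  v <- as.numeric(r$values)
  expect_lt(abs(mean(v) - 1), 0.8)      # spatial mean fluctuates with range
  expect_lt(abs(var(v) / 2 - 1), 0.5)
})

test_that("footprint sampler restricts fields exactly when noiseless", {
  f <- tiny_field(16, seed = 2, mean = 10)
  fp <- sample_footprints(list(m = f), along_m = 60, across_m = 120,
                          noise_sd = 0, seed = 5)
  expect_gt(nrow(fp), 10)
  expect_equal(fp$m, raster_at(f, fp$x, fp$y))
  expect_false(any(duplicated(fp$id)))
  expect_true(all(fp$sensitivity >= 0 & fp$sensitivity <= 1))
})

test_that("track geometry yields the expected footprint count", {
  # 6 km x 6 km domain, 600 m across-track, 60 m along-track:
  # ~10 tracks x ~100 footprints each before QC
  g <- grid_spec(0, cell_size = 30, n_rows = 200, n_cols = 200)
  f <- raster_layer(g, 1)
  counts <- vapply(1:5, function(s)
    nrow(sample_footprints(list(m = f), along_m = 60, across_m = 600,
                           noise_sd = 0, seed = s)), 0L)
  expect_true(all(counts > 700 & counts < 1300))
  # spacing beyond the extent: empty with a warning
  small <- raster_layer(tiny_grid(4), 1)
  expect_warning(e <- sample_footprints(list(m = small), along_m = 200,
                                        across_m = 200, seed = 1),
                 "empty|inside")
  expect_equal(nrow(e), 0)
})

test_that("QC-fail fraction matches its binomial expectation", {
  g <- grid_spec(0, cell_size = 30, n_rows = 130, n_cols = 130)
  f <- raster_layer(g, 1)
  fp <- sample_footprints(list(m = f), along_m = 60, across_m = 60,
                          noise_sd = 0, qc_fail_frac = 0.25, seed = 11)
  n <- nrow(fp)
  expect_gt(n, 3000)
  kept <- nrow(filter_footprints(fp))
  expect_lt(abs(kept - 0.75 * n), 3 * sqrt(n * 0.25 * 0.75))
})

test_that("plot generator honors n, the response, and its seed", {
  f <- tiny_field(16, seed = 3, mean = 50, psill = 25)
  p <- simulate_plots(list(v = f), n = 20,
                      coeffs = list(type = "identity", field = "v"),
                      noise_sd = 0, seed = 2)
  expect_equal(p$volume_per_ha, pmax(raster_at(f, p$x, p$y), 0))
  p143 <- simulate_plots(list(v = f), n = 143,
                         coeffs = list(type = "identity", field = "v"),
                         noise_sd = 5, seed = 2)
  expect_equal(nrow(p143), 143L)
  expect_true(all(p143$volume_per_ha >= 0))
  expect_true(all(p143$mean_dbh > 0))
  expect_error(simulate_plots(list(v = f), n = 16 * 16 + 1), "exceeds")
  expect_identical(simulate_plots(list(v = f), n = 30, seed = 7,
                                  coeffs = list(type = "identity",
                                                field = "v")),
                   simulate_plots(list(v = f), n = 30, seed = 7,
                                  coeffs = list(type = "identity",
                                                field = "v")))
})

test_that("default plot response matches a Monte-Carlo oracle of g", {
  # fields are Gaussian: h ~ N(18, 16+.4), cover ~ N(.55, .021); the
  # analytic mean of g = vmax * h+/(h+ + h50) * clamp(cover) is estimated
  # by an independent 1e5-draw Monte-Carlo oracle
  hf <- tiny_field(40, seed = 21, kind = "exponential", nugget = 0.4,
                   psill = 16, range_m = 900, mean = 18)
  cf <- tiny_field(40, seed = 22, kind = "exponential", nugget = 0.001,
                   psill = 0.02, range_m = 800, mean = 0.55)
  p <- simulate_plots(list(rh98 = hf, cover = cf), n = 500, noise_sd = 15,
                      seed = 1)
  oracle <- withr::with_seed(99, {
    h <- pmax(rnorm(1e5, 18, sqrt(16.4)), 0)
    cv <- pmin(pmax(rnorm(1e5, 0.55, sqrt(0.021)), 0), 1)
    g <- 400 * h / (h + 12) * cv
    # volume is clipped at 0 after noise; emulate the same clipping
    mean(pmax(g + rnorm(1e5, 0, 15), 0))
  })
  # plot locations sample two *correlated spatial fields*; with ~2 effective
  # ranges per side the 500-plot mean wobbles more than iid draws would
  se <- sd(p$volume_per_ha) / sqrt(50)   # conservative effective n
  expect_lt(abs(mean(p$volume_per_ha) - oracle), 3 * se)
})

test_that("QC filter is strict, schema-checked, order-preserving, idempotent", {
  t <- data.frame(id = c("a", "b", "c"), x = 1:3, y = 1:3,
                  sensitivity = c(0.89, 0.90, 0.91), quality_flag = 1L)
  kept <- filter_footprints(t)
  expect_identical(kept$id, "c")      # strictly greater than 0.9
  t2 <- data.frame(id = sprintf("r%02d", 1:100), x = 1:100, y = 1:100,
                   sensitivity = c(rep(0.95, 60), rep(0.95, 40)),
                   quality_flag = c(rep(1L, 60), rep(0L, 40)))
  f1 <- filter_footprints(t2)
  expect_equal(nrow(f1), 60)
  expect_identical(filter_footprints(f1), f1)          # idempotent
  expect_identical(f1$id, t2$id[1:60])                 # order preserved
  expect_equal(nrow(filter_footprints(t2[0, ])), 0)    # empty in, empty out
  expect_error(filter_footprints(data.frame(x = 1)), "sensitivity")
})

test_that("table CSV io roundtrips", {
  f <- tiny_field(8, seed = 1)
  fp <- sample_footprints(list(m = f), along_m = 60, across_m = 120, seed = 3)
  p <- tempfile(fileext = ".csv")
  write_table_csv(fp, p)
  back <- read_table_csv(p)
  expect_equal(back$m, fp$m, tolerance = 1e-12)
  expect_identical(back$quality_flag, fp$quality_flag)
  unlink(p)
})
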