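# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; no stored fixtures.

tiny_grid <- function(n = 16, cell = 30) {
  grid_spec(0, cell_size = cell, n_rows = n, n_cols = n)
}

tiny_field <- function(n = 16, seed = 1, kind = "spherical", nugget = 0,
                       psill = 1, range_m = 300, mean = 0) {
  simulate_gaussian_field(tiny_grid(n), vgm_model(kind, nugget, psill,
                                                  range_m), mean, seed)
}

random_points <- function(n, seed, extent = 480) {
  withr::with_seed(seed, data.frame(x = runif(n, 0, extent),
                                    y = runif(n, 0, extent),
                                    z = rnorm(n)))
}

# Pair-enumeration semivariogram oracle: explicit double loop.
oracle_variogram <- function(x, y, z, lag_width, max_lag) {
  n <- length(x)
  sums <- counts <- dsums <- numeric(ceiling(max_lag / lag_width))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d > 0 && d <= max_lag) {
      b <- floor(d / lag_width) + 1
      sums[b] <- sums[b] + (z[i] - z[j])^2 / 2
      dsums[b] <- dsums[b] + d
      counts[b] <- counts[b] + 1
    }
  }
  keep <- counts > 0
  list(lag_centers = (which(keep) - 0.5) * lag_width,
       lag_means = dsums[keep] / counts[keep],
       semivariances = sums[keep] / counts[keep],
       pair_counts = counts[keep])
}

# Independent GLCM oracle for the center cell of a quantized patch:
# explicit pair tabulation over the four orientations (optionally negated),
# then direct feature formulas on the dense normalized matrix.
oracle_glcm_center <- function(q, levels, displacement = 1, negate = FALSE) {
  d <- if (negate) -displacement else displacement
  offs <- list(c(0, d), c(d, 0), c(d, d), c(d, -d))
  P <- matrix(0, levels, levels)
  n <- nrow(q)
  for (o in offs) for (r in 1:n) for (cc in 1:n) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= n) {
      P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
      P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
    }
  }
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  mu <- sum(i * P)
  s2 <- sum((i - mu)^2 * P)
  pz <- P[P > 0]
  c(glcm_mean = mu, glcm_variance = s2,
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_contrast = sum(P * (i - j)^2),
    glcm_dissimilarity = sum(P * abs(i - j)),
    glcm_entropy = -sum(pz * log(pz)), glcm_asm = sum(P^2),
    glcm_correlation = if (s2 > 0) sum((i - mu) * (j - mu) * P) / s2 else 1)
}

# Small learner-ready regression fixture.
toy_xy <- function(n = 120, seed = 1, noise = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
    y <- 2 * X[, 1] + sin(3 * X[, 2]) + 0.5 * X[, 3] * X[, 1] +
      rnorm(n, 0, noise)
    list(X = X, y = y)
  })
}

expect_raster_equal <- function(a, b, tol = 1e-12) {
  expect_true(same_grid(a$grid, b$grid))
  expect_equal(a$values, b$values, tolerance = tol)
}
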