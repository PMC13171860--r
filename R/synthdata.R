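# Synthetic world generator: stationary Gaussian random fields with a known
# variogram, LiDAR-like footprint sampling along parallel tracks, field
# plots with a nonlinear volume response, and footprint quality control.

#' Simulate a stationary Gaussian random field
#'
#' The spatially structured component (partial sill) is generated either by
#' exact dense Cholesky factorization of the covariance implied by the
#' variogram (grids up to `chol_max_cells` cells) or, above that, by FFT
#' circulant embedding (exact when the embedding is positive semidefinite;
#' negative eigenvalues are clamped to zero with a warning). The nugget is
#' added as independent white noise. The method used is recorded in
#' `attr(, "sim_method")`.
#'
#' @param grid A [grid_spec()].
#' @param model A [vgm_model()]; its theoretical variogram is the target.
#' @param mean Field mean.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @param method `"auto"`, `"chol"` or `"fft"`.
#' @param chol_max_cells Cell-count cutoff for the dense exact method.
#' @return A [raster_layer()].
#' @export
simulate_gaussian_field <- function(grid, model, mean = 0, seed = 1,
                                    method = c("auto", "chol", "fft"),
                                    chol_max_cells = 4096) {
  stopifnot(inherits(grid, "cs_grid"), inherits(model, "cs_vgm"))
  method <- match.arg(method)
  n_cells <- grid$n_rows * grid$n_cols
  if (method == "auto")
    method <- if (n_cells <= chol_max_cells) "chol" else "fft"
  structured <- vgm_model(model$kind, nugget = 0, psill = model$psill,
                          range_m = model$range_m)
  vals <- with_seed(seed, {
    z <- if (model$psill == 0) {
      matrix(0, grid$n_rows, grid$n_cols)
    } else if (method == "chol") {
      rc <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
      cc <- cell_centers(grid, rc$row, rc$col)
      d <- as.matrix(dist(cc))
      C <- vgm_covariance(structured, d)
      L <- chol(C + diag(1e-10 * model$psill, n_cells))
      matrix(as.numeric(crossprod(L, rnorm(n_cells))),
             grid$n_rows, grid$n_cols)
    } else {
      sim_field_fft(grid, structured)
    }
    if (model$nugget > 0)
      z <- z + matrix(rnorm(n_cells, 0, sqrt(model$nugget)),
                      grid$n_rows, grid$n_cols)
    z + mean
  })
  out <- raster_layer(grid, vals)
  attr(out, "sim_method") <- method
  out
}

# Dietrich & Newsam circulant embedding on a doubled (power-of-two) torus.
sim_field_fft <- function(grid, model) {
  m1 <- 2^ceiling(log2(2 * grid$n_rows))
  m2 <- 2^ceiling(log2(2 * grid$n_cols))
  cs <- grid$cell_size
  dr <- pmin(0:(m1 - 1), m1 - 0:(m1 - 1)) * cs
  dc <- pmin(0:(m2 - 1), m2 - 0:(m2 - 1)) * cs
  d <- sqrt(outer(dr^2, dc^2, `+`))
  C <- matrix(vgm_covariance(model, as.numeric(d)), m1, m2)
  lambda <- Re(stats::fft(C))
  if (min(lambda) < -1e-8 * max(lambda))
    warning("circulant embedding not PSD; clamping negative eigenvalues ",
            "(approximate simulation)")
  lambda[lambda < 0] <- 0
  eps <- matrix(complex(real = rnorm(m1 * m2), imaginary = rnorm(m1 * m2)),
                m1, m2)
  f <- stats::fft(sqrt(lambda) * eps) / sqrt(m1 * m2)
  Re(f)[seq_len(grid$n_rows), seq_len(grid$n_cols)]
}

#' Sample LiDAR-like footprints along parallel tracks
#'
#' Footprints are placed on parallel tracks with the stated across-track and
#' along-track spacings (defaults emulate a spaceborne profiling LiDAR:
#' ~60 m along track, ~600 m between tracks), with a small seeded random
#' orientation and phase. Each metric is the underlying field value at the
#' footprint center plus Gaussian noise. A configurable fraction of
#' footprints is marked to fail quality control (half via low sensitivity,
#' half via `quality_flag = 0`).
#'
#' @param fields Named list of [raster_layer()]s sharing one grid.
#' @param along_m,across_m Along-track / across-track spacing (m).
#' @param noise_sd Metric noise standard deviation: a scalar applied to all
#'   metrics, or a vector named by metric (fields differ by orders of
#'   magnitude, so per-metric noise is the realistic choice).
#' @param qc_fail_frac Expected fraction of footprints failing QC.
#' @param seed Integer seed.
#' @param max_tilt_deg Max random track tilt from north (degrees).
#' @return A data.frame footprint table: `id, x, y, <metrics...>,
#'   sensitivity, quality_flag`.
#' @export
sample_footprints <- function(fields, along_m = 60, across_m = 600,
                              noise_sd = 0, qc_fail_frac = 0.1, seed = 1,
                              max_tilt_deg = 8) {
  stopifnot(is.list(fields), length(fields) >= 1)
  grid <- fields[[1]]$grid
  for (f in fields) if (!same_grid(f$grid, grid))
    stop_schema("all fields must share one grid")
  w <- grid$n_cols * grid$cell_size
  h <- grid$n_rows * grid$cell_size
  if (across_m > max(w, h) && along_m > max(w, h)) {
    warning("track spacing exceeds grid extent; returning empty table")
    return(empty_footprints(names(fields)))
  }
  with_seed(seed, {
    theta <- runif(1, -max_tilt_deg, max_tilt_deg) * pi / 180
    u <- c(sin(theta), cos(theta))          # along-track (northish)
    v <- c(cos(theta), -sin(theta))         # across-track
    cx <- grid$origin_x + w / 2
    cy <- grid$origin_y - h / 2
    half_diag <- sqrt(w^2 + h^2) / 2
    off_phase <- runif(1, 0, across_m)
    offs <- seq(-half_diag - off_phase, half_diag, by = across_m) + off_phase
    s_phase <- runif(1, 0, along_m)
    ss <- seq(-half_diag - s_phase, half_diag, by = along_m) + s_phase
    pts <- expand.grid(off = offs, s = ss)
    x <- cx + pts$off * v[1] + pts$s * u[1]
    y <- cy + pts$off * v[2] + pts$s * u[2]
    inside <- x >= grid$origin_x & x <= grid$origin_x + w &
      y <= grid$origin_y & y >= grid$origin_y - h
    x <- x[inside]; y <- y[inside]
    n <- length(x)
    if (n == 0) {
      warning("no footprints fall inside the grid")
      return(empty_footprints(names(fields)))
    }
    tab <- data.frame(id = sprintf("fp%06d", seq_len(n)), x = x, y = y)
    for (nm in names(fields)) {
      sdv <- if (!is.null(names(noise_sd))) noise_sd[[nm]] %||% 0
             else noise_sd
      tab[[nm]] <- raster_at(fields[[nm]], x, y) + rnorm(n, 0, sdv)
    }
    fail <- runif(n) < qc_fail_frac
    fail_kind <- runif(n) < 0.5             # TRUE: sensitivity, FALSE: flag
    tab$sensitivity <- ifelse(fail & fail_kind, runif(n, 0.5, 0.9),
                              runif(n, 0.905, 1))
    tab$quality_flag <- ifelse(fail & !fail_kind, 0L, 1L)
    tab
  })
}

empty_footprints <- function(metric_names) {
  tab <- data.frame(id = character(0), x = numeric(0), y = numeric(0))
  for (nm in metric_names) tab[[nm]] <- numeric(0)
  tab$sensitivity <- numeric(0)
  tab$quality_flag <- integer(0)
  tab
}

#' Footprint quality control
#'
#' Retains records with `sensitivity > sensitivity_min` (strict inequality)
#' and, if required, `quality_flag == 1`. Order is preserved and the filter
#' is idempotent.
#'
#' @param t Footprint table (needs `sensitivity` and `quality_flag`).
#' @param sensitivity_min Threshold (default 0.9; a record at exactly 0.9 is
#'   dropped).
#' @param require_quality Require `quality_flag == 1`.
#' @return Filtered table.
#' @export
filter_footprints <- function(t, sensitivity_min = 0.9, require_quality = TRUE) {
  if (!all(c("sensitivity", "quality_flag") %in% names(t)))
    stop_schema("footprint table lacks sensitivity/quality_flag columns")
  keep <- t$sensitivity > sensitivity_min
  if (require_quality) keep <- keep & t$quality_flag == 1
  t[keep, , drop = FALSE]
}

#' Simulate calibration plots with a nonlinear volume response
#'
#' Plot locations are drawn uniformly over distinct grid cells. Stand volume
#' is `g(fields at location) + noise`, clipped at zero, where `g` is either
#' the identity on one field or (default) a saturating response
#' `vmax * h / (h + h50) * clamp(cover, 0, 1)` of a canopy-height-like field
#' `h` and a cover-like fraction — volume saturates in tall closed stands,
#' which is the behaviour that makes optical predictors saturate in the
#' first place. Mean DBH is generated as an increasing noisy function of
#' volume.
#'
#' @param fields Named list of [raster_layer()]s on one grid.
#' @param n Number of plots (<= number of grid cells).
#' @param coeffs Response spec: `list(type = "saturating", height_field =,
#'   cover_field =, vmax = 400, h50 = 12)` or
#'   `list(type = "identity", field =)`.
#' @param noise_sd Volume noise sd (m3/ha).
#' @param seed Integer seed.
#' @return A data.frame plot table: `id, x, y, mean_dbh, volume_per_ha,
#'   stand_age`.
#' @export
simulate_plots <- function(fields, n = 143,
                           coeffs = list(type = "saturating",
                                         height_field = names(fields)[1],
                                         cover_field = names(fields)[2],
                                         vmax = 400, h50 = 12),
                           noise_sd = 15, seed = 1) {
  stopifnot(n >= 1)
  grid <- fields[[1]]$grid
  n_cells <- grid$n_rows * grid$n_cols
  if (n > n_cells) stop("n exceeds the number of grid cells")
  with_seed(seed, {
    cells <- sample.int(n_cells, n)
    row <- (cells - 1L) %% grid$n_rows + 1L
    col <- (cells - 1L) %/% grid$n_rows + 1L
    cc <- cell_centers(grid, row, col)
    g <- plot_response(fields, cc$x, cc$y, coeffs)
    vol <- pmax(g + rnorm(n, 0, noise_sd), 0)
    dbh <- pmax(8 + 0.08 * vol + rnorm(n, 0, 1.5), 5)
    data.frame(id = sprintf("plot%04d", seq_len(n)), x = cc$x, y = cc$y,
               mean_dbh = dbh, volume_per_ha = vol,
               stand_age = round(pmax(rnorm(n, 35, 8), 10)))
  })
}

# The documented nonlinear response g used by simulate_plots.
plot_response <- function(fields, x, y, coeffs) {
  type <- coeffs$type %||% "saturating"
  if (type == "identity") {
    raster_at(fields[[coeffs$field]], x, y)
  } else if (type == "saturating") {
    h <- pmax(raster_at(fields[[coeffs$height_field]], x, y), 0)
    cov <- raster_at(fields[[coeffs$cover_field]], x, y)
    cov <- pmin(pmax(cov, 0), 1)
    (coeffs$vmax %||% 400) * h / (h + (coeffs$h50 %||% 12)) * cov
  } else stop("unknown response type: ", type)
}

#' Read/write footprint and plot tables as CSV
#'
#' @param t Table (data.frame).
#' @param path CSV path (header row, columns as produced by the generators).
#' @name table_io
#' @export
write_table_csv <- function(t, path) {
  write.csv(t, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_table_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)
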