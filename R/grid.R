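# Lightweight north-up raster container on a projected (metric) grid.
# Cell (r, c), 1-based, has center x = origin_x + (c - 0.5) * cell_size,
# y = origin_y - (r - 0.5) * cell_size: y decreases with row index.

#' Define a regular north-up analysis grid
#'
#' @param origin_x,origin_y Map coordinates (m) of the upper-left corner of
#'   the upper-left cell.
#' @param cell_size Cell edge length in metres (default 30, the common
#'   analysis lattice used for fusing optical, terrain and LiDAR predictors).
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param crs_tag Free-text label for the projected CRS.
#' @return An object of class `cs_grid`.
#' @export
grid_spec <- function(origin_x = 0, origin_y = NULL, cell_size = 30,
                      n_rows = 1, n_cols = 1, crs_tag = "local-metric") {
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (is.null(origin_y)) origin_y <- n_rows * cell_size
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
                 crs_tag = crs_tag),
            class = "cs_grid")
}

#' Construct a raster on a grid
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix (`n_rows x n_cols`) or a scalar recycled to
#'   the grid shape. `NA` marks nodata internally.
#' @param nodata Sentinel written on export (default -9999).
#' @return An object of class `cs_raster`.
#' @export
raster_layer <- function(grid, values = NA_real_, nodata = -9999) {
  stopifnot(inherits(grid, "cs_grid"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop_schema("values shape %dx%d does not match grid %dx%d",
                nrow(values), ncol(values), grid$n_rows, grid$n_cols)
  structure(list(grid = grid, values = values, nodata = nodata),
            class = "cs_raster")
}

#' @export
print.cs_grid <- function(x, ...) {
  cat(sprintf("<cs_grid %dx%d @ %gm, origin (%g, %g), crs '%s'>\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_tag))
  invisible(x)
}

#' @export
print.cs_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<cs_raster %dx%d @ %gm; valid %d; range [%g, %g]>\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(c(a$origin_x - b$origin_x, a$origin_y - b$origin_y,
            a$cell_size - b$cell_size)) < tol) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Cell-center coordinates
#'
#' @param grid A [grid_spec()].
#' @param rows,cols 1-based indices (vectors, recycled together).
#' @return data.frame with columns x, y.
#' @export
cell_centers <- function(grid, rows, cols) {
  data.frame(x = grid$origin_x + (cols - 0.5) * grid$cell_size,
             y = grid$origin_y - (rows - 0.5) * grid$cell_size)
}

#' Map coordinates to cell indices (cell-center semantics)
#'
#' Points outside the grid get NA indices.
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors.
#' @return data.frame with columns row, col.
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Raster values at arbitrary points (cell-center lookup)
#' @param r A [raster_layer()].
#' @param x,y Point coordinates; NA returned outside the extent.
#' @return Numeric vector.
#' @export
raster_at <- function(r, x, y) {
  idx <- cell_index(r$grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Nearest-neighbor resampling between grids
#'
#' Each target cell takes the value of the source cell whose center is
#' nearest to the target cell center; no new intermediate values are ever
#' created. Target cells whose center falls outside the source extent are
#' nodata.
#'
#' @param r Source [raster_layer()].
#' @param target Target [grid_spec()].
#' @return A `cs_raster` on `target`.
#' @export
resample_nearest <- function(r, target) {
  stopifnot(inherits(r, "cs_raster"), inherits(target, "cs_grid"))
  src <- r$grid
  tx <- src$origin_x + c(0, src$n_cols) * src$cell_size
  ty <- src$origin_y - c(src$n_rows, 0) * src$cell_size
  ox <- target$origin_x + c(0, target$n_cols) * target$cell_size
  oy <- target$origin_y - c(target$n_rows, 0) * target$cell_size
  if (ox[1] >= tx[2] || ox[2] <= tx[1] || oy[1] >= ty[2] || oy[2] <= ty[1]) {
    warning("source and target extents are disjoint; returning all-nodata")
    return(raster_layer(target, NA_real_, r$nodata))
  }
  cc_x <- target$origin_x + (seq_len(target$n_cols) - 0.5) * target$cell_size
  cc_y <- target$origin_y - (seq_len(target$n_rows) - 0.5) * target$cell_size
  # nearest source center along each axis (clamped only when inside extent)
  col <- round((cc_x - src$origin_x) / src$cell_size + 0.5)
  row <- round((src$origin_y - cc_y) / src$cell_size + 0.5)
  col_ok <- cc_x >= tx[1] & cc_x <= tx[2]
  row_ok <- cc_y >= ty[1] & cc_y <= ty[2]
  col <- pmin(pmax(col, 1), src$n_cols)
  row <- pmin(pmax(row, 1), src$n_rows)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  rr <- which(row_ok); cc <- which(col_ok)
  if (length(rr) && length(cc))
    out[rr, cc] <- r$values[row[rr], col[cc], drop = FALSE]
  raster_layer(target, out, r$nodata)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header then rows top-down).
#' @param r A [raster_layer()].
#' @param path Output file path.
#' @export
write_ascii_grid <- function(r, path) {
  g <- r$grid
  hdr <- c(sprintf("ncols %d", g$n_cols), sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$cell_size),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", r$nodata))
  v <- r$values
  v[!is.finite(v)] <- r$nodata
  lines <- apply(v, 1, function(row) paste(format(row, trim = TRUE,
                                                  digits = 10), collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param crs_tag Label attached to the resulting grid.
#' @return A `cs_raster` (nodata cells become NA).
#' @export
read_ascii_grid <- function(path, crs_tag = "local-metric") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- t(vapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]),
    numeric(hdr$ncols), USE.NAMES = FALSE))
  nd <- hdr$nodata_value %||% -9999
  vals[vals == nd] <- NA_real_
  g <- grid_spec(origin_x = hdr$xllcorner,
                 origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                 cell_size = hdr$cellsize, n_rows = hdr$nrows,
                 n_cols = hdr$ncols, crs_tag = crs_tag)
  raster_layer(g, vals, nd)
}
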