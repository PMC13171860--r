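# Temporal and areal harmonization of plot volumes: stand density index,
# growth-model projection between survey and imagery years, and per-pixel
# areal scaling.

#' Growth-model parameters
#'
#' Localized stand-volume growth model for the study species. `a1..a5` are
#' the published coefficients; `si` is the site index (regional average
#' 18.39); `d0` the standard diameter (12 cm); `sdi_coef` and `sdi_exp` the
#' stand-density-index constant and exponent.
#'
#' @return Named list of parameters.
#' @export
growth_params <- function() {
  list(a1 = 17.6139, a2 = 0.06798776, a3 = -0.39435932, a4 = -1.5839,
       a5 = 0.0906281, si = 18.39, d0 = 12, sdi_coef = 407181.974,
       sdi_exp = -2.209)
}

#' Stand density index
#'
#' SDI = 407181.974 * (D0 / D)^(-2.209). At D = D0 the power term is 1 and
#' the SDI equals the coefficient itself. Strictly increasing in D.
#'
#' @param d Plot mean diameter (cm, > 0); vectorized.
#' @param d0 Standard diameter (cm, default 12).
#' @param params Coefficient list (see [growth_params()]).
#' @return SDI values.
#' @export
stand_density_index <- function(d, d0 = growth_params()$d0,
                                params = growth_params()) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("mean diameter must be > 0")
  params$sdi_coef * (d0 / d)^params$sdi_exp
}

#' Stand volume from the growth model
#'
#' V' = a1 * SI^a2 / (1 - a3 * SDI^a4 * exp(-a5 * t)). With the published
#' coefficients (a3 < 0) the denominator is > 1 and decreases toward 1 as t
#' grows, so V' increases monotonically to the asymptote a1 * SI^a2.
#'
#' @param si Site index (> 0).
#' @param sdi Stand density index (> 0).
#' @param t Stand age in years (>= 0).
#' @param params Coefficient list.
#' @return V' in m3/ha.
#' @export
stand_volume <- function(si, sdi, t, params = growth_params()) {
  stopifnot(all(si > 0), all(sdi > 0), all(t >= 0))
  den <- 1 - params$a3 * sdi^params$a4 * exp(-params$a5 * t)
  if (any(den <= 0)) stop("growth-model denominator <= 0 (outside domain)")
  params$a1 * si^params$a2 / den
}

#' Project a measured plot volume forward in time
#'
#' Ratio projection: v_projected = v_base * V'(t_base + dt) / V'(t_base),
#' applying the growth model's relative growth between the two ages to the
#' measured volume.
#'
#' @param v_base Measured volume (m3/ha).
#' @param si Site index.
#' @param sdi Stand density index.
#' @param t_base Stand age at measurement (years); required — the model is a
#'   function of age, not calendar year.
#' @param dt Years to project forward.
#' @param params Coefficient list.
#' @return Projected volume (m3/ha).
#' @export
project_volume <- function(v_base, si, sdi, t_base, dt,
                           params = growth_params()) {
  if (missing(t_base) || any(is.na(t_base)))
    stop("t_base (stand age at measurement) is required for projection")
  stopifnot(all(v_base >= 0), all(dt >= 0))
  v_base * stand_volume(si, sdi, t_base + dt, params) /
    stand_volume(si, sdi, t_base, params)
}

#' Areal scaling from per-hectare to per-pixel volume
#'
#' v_per_cell = v_per_ha * cell_size^2 / 10000; at 30 m the factor is
#' 900/10000 = 0.09, and a 100 m cell is exactly one hectare.
#'
#' @param v_per_ha Volume per hectare (>= 0).
#' @param cell_size Cell edge (m, default 30).
#' @return Volume per pixel (m3).
#' @export
areal_scale <- function(v_per_ha, cell_size = 30) {
  stopifnot(all(v_per_ha >= 0, na.rm = TRUE))
  v_per_ha * cell_size^2 / 10000
}

#' Harmonize a plot table in one step
#'
#' Computes the SDI from mean DBH, projects the measured volume forward by
#' `dt` years using the stand age column, and appends the per-pixel volume.
#'
#' @param plots Plot table with `mean_dbh`, `volume_per_ha`, `stand_age`.
#' @param dt Projection horizon in years.
#' @param cell_size Analysis cell size (m).
#' @param si Site index (default regional average).
#' @return The table with added columns `sdi`, `volume_projected`,
#'   `volume_per_cell`.
#' @export
harmonize_plots <- function(plots, dt = 3, cell_size = 30,
                            si = growth_params()$si) {
  if (!all(c("mean_dbh", "volume_per_ha") %in% names(plots)))
    stop_schema("plot table needs mean_dbh and volume_per_ha")
  if (!"stand_age" %in% names(plots))
    stop("stand_age column required: supply the stand age at measurement")
  out <- plots
  out$sdi <- stand_density_index(plots$mean_dbh)
  out$volume_projected <- project_volume(plots$volume_per_ha, si, out$sdi,
                                         plots$stand_age, dt)
  out$volume_per_cell <- areal_scale(out$volume_projected, cell_size)
  out
}
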