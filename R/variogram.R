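# Variography: empirical semivariograms, theoretical model fitting, and the
# nugget-to-sill classification of spatial dependence.

#' Define a theoretical variogram model
#'
#' @param kind One of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget Nugget variance C0 (>= 0): unresolved micro-scale variance
#'   plus measurement error, the limit of the semivariance as h -> 0+.
#' @param psill Partial sill C (>= 0): spatially structured variance; the
#'   total sill is C0 + C.
#' @param range_m Range in metres (> 0). For the spherical model the sill is
#'   reached exactly at the range; for exponential and Gaussian the range is
#'   the *effective* range at which the structured part reaches 95% of C.
#' @return An object of class `cs_vgm`.
#' @export
vgm_model <- function(kind = c("spherical", "exponential", "gaussian"),
                      nugget = 0, psill = 1, range_m = 1) {
  kind <- match.arg(kind)
  if (!is.finite(nugget) || nugget < 0) stop("nugget must be >= 0")
  if (!is.finite(psill) || psill < 0) stop("partial sill must be >= 0")
  if (!is.finite(range_m) || range_m <= 0) stop("range must be > 0")
  structure(list(kind = kind, nugget = nugget, psill = psill,
                 range_m = range_m, sill = nugget + psill,
                 structural_ratio =
                   if (nugget + psill > 0) nugget / (nugget + psill) else 0),
            class = "cs_vgm")
}

#' @export
print.cs_vgm <- function(x, ...) {
  cat(sprintf("<cs_vgm %s: C0=%g C=%g range=%gm (ratio %.3f)>\n",
              x$kind, x$nugget, x$psill, x$range_m, x$structural_ratio))
  invisible(x)
}

#' Theoretical semivariance gamma(h)
#'
#' gamma(0) = 0 by definition; for h > 0 the nugget enters in full.
#' Exponential and Gaussian use the effective-range convention (95% of the
#' partial sill at `range_m`), i.e. gamma_exp = C0 + C(1 - exp(-3h/a)) and
#' gamma_gau = C0 + C(1 - exp(-3h^2/a^2)).
#'
#' @param m A [vgm_model()].
#' @param h Nonnegative lag distances (m).
#' @return Semivariances, same length as `h`.
#' @export
semivariance <- function(m, h) {
  stopifnot(inherits(m, "cs_vgm"))
  if (any(h < 0)) stop("negative lag distance")
  a <- m$range_m
  s <- switch(m$kind,
    spherical   = ifelse(h >= a, 1, 1.5 * (h / a) - 0.5 * (h / a)^3),
    exponential = 1 - exp(-3 * h / a),
    gaussian    = 1 - exp(-3 * (h / a)^2))
  out <- m$nugget + m$psill * s
  out[h == 0] <- 0
  out
}

# Stationary covariance implied by the model: C(h) = sill - gamma(h), with
# the full sill (incl. nugget) at h = 0.
vgm_covariance <- function(m, h) {
  out <- m$sill - semivariance(m, h)
  out[h == 0] <- m$sill
  out
}

#' Empirical (Matheron) semivariogram
#'
#' For each lag bin, gamma(h) = (1 / 2N(h)) * sum (z_i - z_j)^2 over point
#' pairs whose separation falls in the bin. Bins with zero pairs are dropped.
#'
#' @param x,y Point coordinates (m).
#' @param z Values at the points.
#' @param lag_width Bin width (m, > 0). Default: half the mean
#'   nearest-neighbor distance.
#' @param max_lag Largest pair distance considered. Default: half the domain
#'   diagonal.
#' @return An object of class `cs_empvgm` with `lag_centers` (bin
#'   midpoints), `lag_means` (pair-weighted mean distance per bin, the
#'   abscissa model fits use), `semivariances`, `pair_counts`.
#' @export
empirical_variogram <- function(x, y, z, lag_width = NULL, max_lag = NULL) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 points")
  d <- as.matrix(dist(cbind(x, y)))
  du <- d[upper.tri(d)]
  if (all(du == 0)) stop("all points coincident: no positive lags")
  if (is.null(max_lag))
    max_lag <- sqrt(diff(range(x))^2 + diff(range(y))^2) / 2
  if (is.null(lag_width)) {
    diag(d) <- Inf
    lag_width <- mean(apply(d, 1, min)) / 2
  }
  if (lag_width <= 0) stop("lag_width must be > 0")
  g <- outer(z, z, `-`)[upper.tri(d)]^2 / 2
  keep <- du > 0 & du <= max_lag
  du <- du[keep]; g <- g[keep]
  bin <- floor(du / lag_width) + 1L
  counts <- tabulate(bin)
  sums <- vapply(seq_along(counts), function(b) sum(g[bin == b]), 0.0)
  dsum <- vapply(seq_along(counts), function(b) sum(du[bin == b]), 0.0)
  nz <- counts > 0L
  structure(list(lag_centers = (which(nz) - 0.5) * lag_width,
                 lag_means = dsum[nz] / counts[nz],
                 semivariances = sums[nz] / counts[nz],
                 pair_counts = counts[nz]),
            class = "cs_empvgm")
}

# One weighted least-squares fit for one model kind; deterministic
# multi-start over a fixed grid of initial values. Fits against the
# pair-weighted mean lag where available (bin midpoints otherwise).
fit_one_vgm <- function(ev, kind, weights) {
  h <- ev$lag_means %||% ev$lag_centers; g <- ev$semivariances
  s_tot <- max(g); h_max <- max(h)
  obj <- function(p) {
    m <- vgm_model(kind, nugget = p[1], psill = p[2], range_m = p[3])
    sum(weights * (semivariance(m, h) - g)^2)
  }
  starts <- expand.grid(n0 = c(0, 0.25 * s_tot),
                        c0 = c(0.5, 1) * max(s_tot, 1e-12),
                        a0 = c(0.25, 0.5, 1) * h_max)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
            lower = c(0, 0, 1e-6 * h_max),
            upper = c(2 * max(s_tot, 1e-12), 4 * max(s_tot, 1e-12), 10 * h_max)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  m <- vgm_model(kind, nugget = best$par[1], psill = best$par[2],
                 range_m = best$par[3])
  rss <- sum((semivariance(m, h) - g)^2)      # unweighted RSS, reported
  tss <- sum((g - mean(g))^2)
  r2 <- if (tss > 0) 1 - rss / tss else if (rss < 1e-12) 1 else -Inf
  list(model = m, r2 = r2, rss = rss, kind = kind, ok = TRUE)
}

#' Fit theoretical variogram models to an empirical variogram
#'
#' Each candidate kind is fitted by (by default Cressie pair-count-weighted)
#' least squares on the (lag, semivariance) points; the report retains the
#' best kind by highest R^2, ties broken by lower RSS, then by the fixed
#' order spherical, exponential, gaussian. R^2 is 1 - RSS/TSS about the mean
#' empirical semivariance.
#'
#' @param ev An [empirical_variogram()].
#' @param kinds Model kinds to try.
#' @param weighting `"cressie"` (pair counts N(h)) or `"ols"`.
#' @return List with `best` (model, r2, rss) and `candidates`.
#' @export
fit_variogram <- function(ev, kinds = c("spherical", "exponential", "gaussian"),
                          weighting = c("cressie", "ols")) {
  stopifnot(inherits(ev, "cs_empvgm"))
  weighting <- match.arg(weighting)
  if (length(ev$lag_centers) < 4) stop("need >= 4 usable lags to fit")
  w <- if (weighting == "cressie") ev$pair_counts else rep(1, length(ev$pair_counts))
  cands <- lapply(kinds, function(k) fit_one_vgm(ev, k, w))
  names(cands) <- kinds
  ok <- !vapply(cands, is.null, TRUE)
  if (!any(ok)) stop("all variogram fits failed")
  cands <- cands[ok]
  r2 <- vapply(cands, `[[`, 0.0, "r2")
  rss <- vapply(cands, `[[`, 0.0, "rss")
  ord <- order(-r2, rss, match(names(cands), c("spherical", "exponential",
                                               "gaussian")))
  list(best = cands[[ord[1]]], candidates = cands)
}

#' Classify spatial dependence from the nugget-to-sill ratio
#'
#' Ratio C0/(C0+C) < 0.25 -> strong; 0.25–0.75 -> moderate; > 0.75 -> weak.
#'
#' @param m A [vgm_model()] or a bare numeric ratio in `[0, 1]`.
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
classify_spatial_dependence <- function(m) {
  ratio <- if (inherits(m, "cs_vgm")) m$structural_ratio else as.numeric(m)
  stopifnot(is.finite(ratio), ratio >= 0, ratio <= 1)
  if (ratio < 0.25) "strong" else if (ratio <= 0.75) "moderate" else "weak"
}
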