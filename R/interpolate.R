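# Footprint-to-surface interpolators: ordinary kriging, sequential Gaussian
# conditional simulation, and inverse-distance weighting with an optimized
# exponent, plus the hold-out evaluation gate.

dedup_points <- function(x, y, z) {
  key <- paste(signif(x, 12), signif(y, 12))
  if (!anyDuplicated(key)) return(list(x = x, y = y, z = z))
  agg <- aggregate(list(z = z), by = list(key = key), FUN = mean)
  first <- !duplicated(key)
  ord <- match(unique(key), agg$key)
  list(x = x[first], y = y[first], z = agg$z[ord])
}

#' Ordinary kriging
#'
#' Solves, at each target, the ordinary-kriging system built from model
#' semivariances of the `max_neighbors` nearest observations under the
#' unbiasedness constraint sum(lambda) = 1. A target coinciding with an
#' observation returns that observation with zero variance (exactness).
#' Duplicate observation locations are deduplicated by averaging.
#'
#' @param x,y,z Observations (coordinates in m, values).
#' @param targets A [grid_spec()] (predict every cell center) or a
#'   data.frame with columns `x, y`.
#' @param model A [vgm_model()].
#' @param max_neighbors Neighborhood size (default 25); `Inf` for global
#'   kriging (all observations in every system).
#' @return List with `estimates` and `variances` (rasters if `targets` is a
#'   grid, numeric vectors otherwise) and `neighbors_used`.
#' @export
ordinary_kriging <- function(x, y, z, targets, model, max_neighbors = 25) {
  stopifnot(inherits(model, "cs_vgm"), length(x) >= 2)
  o <- dedup_points(x, y, z)
  n <- length(o$x)
  k <- min(max_neighbors, n)
  as_grid <- inherits(targets, "cs_grid")
  tp <- if (as_grid) {
    rc <- expand.grid(row = seq_len(targets$n_rows),
                      col = seq_len(targets$n_cols))
    cell_centers(targets, rc$row, rc$col)
  } else as.data.frame(targets)[, c("x", "y")]
  nt <- nrow(tp)
  est <- vars <- numeric(nt)
  obs_xy <- cbind(o$x, o$y)
  global <- k >= n
  # tiny diagonal jitter (implicit micro-nugget) keeps the system well
  # conditioned; the gaussian model needs more because its covariance is
  # analytically smooth and its kriging matrix near rank-deficient when
  # the range exceeds the sampled domain
  jit <- (if (model$kind == "gaussian") 1e-7 else 1e-10) *
    max(model$sill, 1e-12)
  if (global) {
    G <- semivariance(model, as.matrix(dist(obs_xy))) + diag(jit, n)
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
    A_fac <- tryCatch(solve(A), error = function(e)
      stop("singular kriging system after deduplication"))
  }
  for (i in seq_len(nt)) {
    d <- sqrt((o$x - tp$x[i])^2 + (o$y - tp$y[i])^2)
    hit <- which(d < 1e-9)
    if (length(hit)) { est[i] <- o$z[hit[1]]; vars[i] <- 0; next }
    if (global) {
      b <- c(semivariance(model, d), 1)
      lam <- A_fac %*% b
      est[i] <- sum(lam[1:n] * o$z)
      vars[i] <- max(sum(lam * b) - 0, 0)
    } else {
      nb <- order(d)[seq_len(k)]
      G <- semivariance(model, as.matrix(dist(obs_xy[nb, , drop = FALSE]))) +
        diag(jit, k)
      A <- rbind(cbind(G, 1), c(rep(1, k), 0))
      b <- c(semivariance(model, d[nb]), 1)
      lam <- tryCatch(solve(A, b), error = function(e) {
        solve(A + diag(c(rep(1e-10 * max(G), k), 0)), b)
      })
      est[i] <- sum(lam[1:k] * o$z[nb])
      vars[i] <- max(sum(lam * b), 0)
    }
  }
  if (as_grid) {
    list(estimates = raster_layer(targets, matrix(est, targets$n_rows)),
         variances = raster_layer(targets, matrix(vars, targets$n_rows)),
         neighbors_used = k)
  } else list(estimates = est, variances = vars, neighbors_used = k)
}

# Normal-score transform: z -> standard normal scores; returns the transform
# table for the (monotone, piecewise-linear) back-transform.
normal_score <- function(z) {
  r <- rank(z, ties.method = "average")
  ns <- qnorm((r - 0.5) / length(z))
  ord <- order(z)
  list(ns = ns, table_z = z[ord], table_ns = ns[ord])
}

back_transform <- function(ns, tab) {
  out <- approx(tab$table_ns, tab$table_z, xout = ns, rule = 2,
                ties = "ordered")$y
  out
}

#' Sequential Gaussian conditional simulation
#'
#' Visits the unsimulated cells along a seeded random path; at each cell the
#' conditional mean and variance come from simple kriging on the nearest
#' conditioning data (original observations plus previously simulated
#' cells), and a Gaussian value is drawn. Data locations are honored in
#' every realization. By default values are normal-score transformed first
#' and back-transformed after simulation; the variogram model's shape (kind,
#' range, nugget-to-sill ratio) is carried into the Gaussian domain with the
#' sill rescaled to the score variance. Realization `i` derives all its
#' randomness from `(seed, i)`, so stacks are reproducible and extensible.
#'
#' @param x,y,z Conditioning observations.
#' @param grid Simulation [grid_spec()].
#' @param model A [vgm_model()] for the data.
#' @param n_realizations Number of realizations (>= 1).
#' @param seed Integer seed.
#' @param max_neighbors Conditioning neighborhood size (default 16).
#' @param normal_scores Use the normal-score transform (default TRUE).
#' @return List of class `cs_sgcs`: `realizations` (list of rasters),
#'   `model`, `seed`.
#' @export
sgcs <- function(x, y, z, grid, model, n_realizations = 1, seed = 1,
                 max_neighbors = 16, normal_scores = TRUE) {
  stopifnot(inherits(grid, "cs_grid"), inherits(model, "cs_vgm"),
            n_realizations >= 1)
  o <- dedup_points(x, y, z)
  if (model$sill == 0) {
    warning("zero-sill model: returning constant realizations")
    base <- matrix(mean(o$z), grid$n_rows, grid$n_cols)
    idx <- cell_index(grid, o$x, o$y)
    ok <- !is.na(idx$row)
    base[cbind(idx$row[ok], idx$col[ok])] <- o$z[ok]
    reals <- replicate(n_realizations, raster_layer(grid, base),
                       simplify = FALSE)
    return(structure(list(realizations = reals, model = model, seed = seed),
                     class = "cs_sgcs"))
  }
  if (normal_scores) {
    tr <- normal_score(o$z)
    zg <- tr$ns
    s2 <- var(zg)
  } else {
    zg <- o$z
    s2 <- model$sill
  }
  gm <- vgm_model(model$kind, nugget = model$structural_ratio * s2,
                  psill = (1 - model$structural_ratio) * s2,
                  range_m = model$range_m)
  mu <- mean(zg)
  # conditioning cells: average obs per cell, in the Gaussian domain
  idx <- cell_index(grid, o$x, o$y)
  ok <- !is.na(idx$row)
  cell_id <- (idx$col[ok] - 1L) * grid$n_rows + idx$row[ok]
  cond <- tapply(zg[ok], cell_id, mean)
  cond_cells <- as.integer(names(cond))
  n_cells <- grid$n_rows * grid$n_cols
  free_cells <- setdiff(seq_len(n_cells), cond_cells)
  all_rc <- cbind((seq_len(n_cells) - 1L) %% grid$n_rows + 1L,
                  (seq_len(n_cells) - 1L) %/% grid$n_rows + 1L)
  cc <- cell_centers(grid, all_rc[, 1], all_rc[, 2])
  sill0 <- gm$sill
  reals <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    vals <- with_seed(derive_seed(seed, 100L + r), {
      v <- rep(NA_real_, n_cells)
      v[cond_cells] <- cond
      kx <- cc$x; ky <- cc$y
      path <- sample(free_cells)
      n_known <- length(cond_cells)
      kidx <- integer(n_cells); kidx[seq_len(n_known)] <- cond_cells
      for (cell in path) {
        if (n_known == 0L) {
          mean_c <- mu; var_c <- sill0
        } else {
          kk <- kidx[seq_len(n_known)]
          d <- sqrt((kx[kk] - kx[cell])^2 + (ky[kk] - ky[cell])^2)
          nb <- if (n_known > max_neighbors)
            kk[order(d)[seq_len(max_neighbors)]] else kk
          dn <- sqrt((kx[nb] - kx[cell])^2 + (ky[nb] - ky[cell])^2)
          Cm <- vgm_covariance(gm, as.matrix(dist(cbind(kx[nb], ky[nb])))) +
            diag(1e-10 * sill0, length(nb))
          c0 <- vgm_covariance(gm, dn)
          lam <- tryCatch(solve(Cm, c0), error = function(e)
            solve(Cm + diag(1e-8 * sill0, length(nb)), c0))
          mean_c <- mu + sum(lam * (v[nb] - mu))
          var_c <- max(sill0 - sum(lam * c0), 0)
        }
        v[cell] <- rnorm(1, mean_c, sqrt(var_c))
        n_known <- n_known + 1L
        kidx[n_known] <- cell
      }
      v
    })
    if (normal_scores) {
      out <- back_transform(vals, tr)
      out[cond_cells] <- back_transform(cond, tr)
    } else out <- vals
    reals[[r]] <- raster_layer(grid, matrix(out, grid$n_rows))
  }
  structure(list(realizations = reals, model = model, seed = seed),
            class = "cs_sgcs")
}

#' Realization-mean surface of a simulation stack
#' @param stack A `cs_sgcs` object.
#' @return A [raster_layer()].
#' @export
realization_mean <- function(stack) {
  stopifnot(inherits(stack, "cs_sgcs"))
  g <- stack$realizations[[1]]$grid
  m <- Reduce(`+`, lapply(stack$realizations, `[[`, "values")) /
    length(stack$realizations)
  raster_layer(g, m)
}

#' Global coefficient of variation across realizations
#'
#' Per-cell CV = sd/mean across realizations (cells with |mean| below
#' `epsilon` excluded), aggregated by the spatial mean.
#'
#' @param stack A `cs_sgcs` object with >= 2 realizations.
#' @param epsilon Exclusion threshold on |mean| (default 1e-8).
#' @return Scalar global CV.
#' @export
realization_cv <- function(stack, epsilon = 1e-8) {
  stopifnot(inherits(stack, "cs_sgcs"))
  N <- length(stack$realizations)
  if (N < 2) stop("need >= 2 realizations for a CV")
  n_cells <- length(stack$realizations[[1]]$values)
  arr <- matrix(vapply(stack$realizations, function(r) as.numeric(r$values),
                       numeric(n_cells)), nrow = n_cells)
  m <- rowMeans(arr)
  s <- apply(arr, 1, sd)
  keep <- abs(m) >= epsilon
  mean(s[keep] / abs(m[keep]))
}

#' Choose a convergent realization count from a CV trace
#'
#' Simulates `max(candidate_Ns)` realizations (realization i depends only on
#' `(seed, i)`, so CV(N) uses the first N) and returns the smallest N whose
#' global CV changed by at most `tol` from the previous candidate; if none
#' converges, the largest N is returned with `converged = FALSE`.
#'
#' @inheritParams sgcs
#' @param candidate_Ns Increasing candidate counts (>= 2 of them).
#' @param tol Absolute CV-change tolerance.
#' @return List `n`, `converged`, `cv_trace`.
#' @export
select_convergent_n <- function(x, y, z, grid, model, candidate_Ns, tol,
                                seed = 1, max_neighbors = 16,
                                normal_scores = TRUE) {
  if (length(candidate_Ns) < 2) stop("need at least two candidate counts")
  if (is.unsorted(candidate_Ns, strictly = TRUE))
    stop("candidate_Ns must be increasing")
  stack <- sgcs(x, y, z, grid, model, n_realizations = max(candidate_Ns),
                seed = seed, max_neighbors = max_neighbors,
                normal_scores = normal_scores)
  cv <- vapply(candidate_Ns, function(N) {
    sub <- structure(list(realizations = stack$realizations[seq_len(N)],
                          model = model, seed = seed), class = "cs_sgcs")
    realization_cv(sub)
  }, 0.0)
  dcv <- abs(diff(cv))
  hit <- which(dcv <= tol)
  if (length(hit)) {
    list(n = candidate_Ns[hit[1] + 1L], converged = TRUE, cv_trace = cv)
  } else list(n = candidate_Ns[length(candidate_Ns)], converged = FALSE,
              cv_trace = cv)
}

#' Inverse-distance-weighted interpolation
#'
#' Prediction = sum(w_i z_i)/sum(w_i) with w_i = d_i^(-beta). A target at
#' zero distance from an observation returns that observation exactly.
#'
#' @param x,y,z Observations.
#' @param targets A [grid_spec()] or data.frame `x, y`.
#' @param beta Distance exponent (> 0).
#' @param k_neighbors Use only the k nearest observations (default all).
#' @return Raster (grid target) or numeric vector.
#' @export
idw <- function(x, y, z, targets, beta = 2, k_neighbors = Inf) {
  if (length(x) == 0) stop("no observations")
  if (beta <= 0) stop("beta must be > 0")
  as_grid <- inherits(targets, "cs_grid")
  tp <- if (as_grid) {
    rc <- expand.grid(row = seq_len(targets$n_rows),
                      col = seq_len(targets$n_cols))
    cell_centers(targets, rc$row, rc$col)
  } else as.data.frame(targets)[, c("x", "y")]
  D <- outer(tp$x, x, `-`)^2 + outer(tp$y, y, `-`)^2
  D <- sqrt(D)
  if (is.finite(k_neighbors) && k_neighbors < length(x)) {
    keep <- t(apply(D, 1, function(d) {
      th <- sort(d, partial = k_neighbors)[k_neighbors]
      d <= th
    }))
  } else keep <- matrix(TRUE, nrow(D), ncol(D))
  W <- ifelse(keep, D^(-beta), 0)
  pred <- as.numeric(W %*% z) / rowSums(W)
  hit <- which(D < 1e-12, arr.ind = TRUE)
  if (nrow(hit)) pred[hit[, 1]] <- z[hit[, 2]]
  if (as_grid) raster_layer(targets, matrix(pred, targets$n_rows)) else pred
}

idw_cv_rmse <- function(x, y, z, beta, folds, fold_id, k_neighbors = Inf) {
  err2 <- 0
  for (f in seq_len(folds)) {
    te <- fold_id == f
    p <- idw(x[!te], y[!te], z[!te], data.frame(x = x[te], y = y[te]),
             beta = beta, k_neighbors = k_neighbors)
    err2 <- err2 + sum((p - z[te])^2)
  }
  sqrt(err2 / length(z))
}

#' IDW optimizer configuration
#'
#' Defaults follow the stated settings: PSO swarm 15, 50 iterations,
#' inertia 0.8, acceleration c1 = c2 = 1.5, beta initialized in [0.1, 5]
#' and constrained to [0.1, 10]; GA population 15, 50 generations,
#' crossover 0.8, mutation 0.1, same bounds; grid search 0.5–5.0 step 0.1;
#' objective is 5-fold-CV RMSE.
#'
#' @param method `"pso"`, `"ga"` or `"grid"`.
#' @param seed Integer seed.
#' @param cv_folds CV folds (>= 2).
#' @param ... Overrides of the named defaults.
#' @return List of class `cs_idwopt`.
#' @export
idw_optimizer_config <- function(method = c("pso", "ga", "grid"), seed = 1,
                                 cv_folds = 5, ...) {
  cfg <- list(method = match.arg(method), seed = seed, cv_folds = cv_folds,
              init_range = c(0.1, 5.0), bounds = c(0.1, 10.0),
              pso_swarm = 15, pso_iters = 50, pso_omega = 0.8,
              pso_c1 = 1.5, pso_c2 = 1.5,
              ga_pop = 15, ga_gens = 50, ga_pc = 0.8, ga_pm = 0.1,
              grid_from = 0.5, grid_to = 5.0, grid_step = 0.1)
  over <- list(...)
  cfg[names(over)] <- over
  if (cfg$cv_folds < 2) stop("cv_folds must be >= 2")
  if (cfg$bounds[1] > cfg$init_range[1] || cfg$bounds[2] < cfg$init_range[2])
    stop("bounds must contain the init range")
  structure(cfg, class = "cs_idwopt")
}

#' Optimize the IDW distance exponent
#'
#' Minimizes the k-fold cross-validated RMSE of [idw()] over beta using
#' particle-swarm optimization, a real-valued genetic algorithm (tournament
#' selection of size 2, blend crossover, Gaussian mutation with sd = 5% of
#' the bound width) or exhaustive grid search (lowest beta wins ties).
#'
#' @param x,y,z Observations (>= `cv_folds` of them).
#' @param config An [idw_optimizer_config()].
#' @return List `beta`, `objective` (CV RMSE at beta), `trace`, `method`.
#' @export
optimize_beta <- function(x, y, z, config = idw_optimizer_config()) {
  stopifnot(inherits(config, "cs_idwopt"))
  n <- length(z)
  if (n < config$cv_folds) stop("need at least cv_folds observations")
  fold_id <- with_seed(derive_seed(config$seed, "split"),
                       sample(rep(seq_len(config$cv_folds), length.out = n)))
  if (sd(z) == 0) {
    warning("constant observation values: objective is degenerate")
    lb <- if (config$method == "grid") config$grid_from else config$bounds[1]
    return(list(beta = lb, objective = 0, trace = NULL,
                method = config$method))
  }
  obj <- function(b) idw_cv_rmse(x, y, z, b, config$cv_folds, fold_id)
  lo <- config$bounds[1]; hi <- config$bounds[2]
  if (config$method == "grid") {
    betas <- seq(config$grid_from, config$grid_to, by = config$grid_step)
    vals <- vapply(betas, obj, 0.0)
    i <- which.min(vals)            # which.min: first (lowest beta) on ties
    return(list(beta = betas[i], objective = vals[i],
                trace = data.frame(beta = betas, rmse = vals),
                method = "grid"))
  }
  if (config$method == "pso") {
    res <- with_seed(derive_seed(config$seed, "bench"), {
      p <- runif(config$pso_swarm, config$init_range[1], config$init_range[2])
      vmax <- hi - lo
      vel <- runif(config$pso_swarm, -vmax, vmax) * 0.1
      fit <- vapply(p, obj, 0.0)
      pb <- p; pbf <- fit
      g <- p[which.min(fit)]; gf <- min(fit)
      trace <- numeric(config$pso_iters)
      for (it in seq_len(config$pso_iters)) {
        r1 <- runif(config$pso_swarm); r2 <- runif(config$pso_swarm)
        vel <- config$pso_omega * vel + config$pso_c1 * r1 * (pb - p) +
          config$pso_c2 * r2 * (g - p)
        vel <- pmin(pmax(vel, -vmax), vmax)
        p <- pmin(pmax(p + vel, lo), hi)
        fit <- vapply(p, obj, 0.0)
        imp <- fit < pbf
        pb[imp] <- p[imp]; pbf[imp] <- fit[imp]
        if (min(pbf) < gf) { gf <- min(pbf); g <- pb[which.min(pbf)] }
        trace[it] <- gf
      }
      list(beta = g, objective = gf, trace = trace)
    })
    return(c(res, list(method = "pso")))
  }
  # GA
  res <- with_seed(derive_seed(config$seed, "bench"), {
    pop <- runif(config$ga_pop, config$init_range[1], config$init_range[2])
    fit <- vapply(pop, obj, 0.0)
    best <- pop[which.min(fit)]; bestf <- min(fit)
    trace <- numeric(config$ga_gens)
    sd_mut <- 0.05 * (hi - lo)
    for (gen in seq_len(config$ga_gens)) {
      new <- numeric(config$ga_pop)
      for (j in seq_len(config$ga_pop)) {
        c1 <- sample.int(config$ga_pop, 2)   # tournament, size 2
        p1 <- pop[c1[which.min(fit[c1])]]
        c2 <- sample.int(config$ga_pop, 2)
        p2 <- pop[c2[which.min(fit[c2])]]
        child <- if (runif(1) < config$ga_pc) {
          a <- runif(1)
          a * p1 + (1 - a) * p2
        } else p1
        if (runif(1) < config$ga_pm) child <- child + rnorm(1, 0, sd_mut)
        new[j] <- min(max(child, lo), hi)
      }
      new[1] <- best                         # elitism keeps the incumbent
      pop <- new
      fit <- vapply(pop, obj, 0.0)
      if (min(fit) < bestf) { bestf <- min(fit); best <- pop[which.min(fit)] }
      trace[gen] <- bestf
    }
    list(beta = best, objective = bestf, trace = trace)
  })
  c(res, list(method = "ga"))
}

#' Coefficient of determination (1 - SSE/SST)
#' @param obs,pred Equal-length numeric vectors.
#' @return Scalar R^2 (can be negative; NA if obs are constant).
#' @export
r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

#' Hold-out evaluation of an interpolation method
#'
#' Splits footprints into a seeded random train (`split_frac`) and test
#' remainder, builds the surface from the training points only, computes the
#' test R^2 between predictions and observations at the test locations, and
#' flags the variable as retained when R^2 >= `threshold`.
#'
#' @param footprints Footprint table (columns `x`, `y`, and `metric`).
#' @param metric Metric column name.
#' @param method One of `"idw"`, `"pso-idw"`, `"ga-idw"`, `"gs-idw"`,
#'   `"ok"`, `"sgcs"`.
#' @param grid [grid_spec()] used for `"sgcs"` surfaces (test points are
#'   read from the realization-mean surface); other methods predict at the
#'   test points directly.
#' @param model Optional [vgm_model()] for `"ok"`/`"sgcs"`; fitted from the
#'   training points when NULL.
#' @param split_frac Training fraction (default 0.8).
#' @param threshold Retention gate on test R^2 (default 0.5).
#' @param seed Integer seed (split and any stochastic method).
#' @param n_realizations SGCS realization count (default 25).
#' @param max_neighbors Kriging/SGCS neighborhood.
#' @return List of class `cs_interp_report`: `metric, method, r2_test,
#'   n_train, n_test, retained, threshold`.
#' @export
evaluate_interpolation <- function(footprints, metric, method, grid = NULL,
                                   model = NULL, split_frac = 0.8,
                                   threshold = 0.5, seed = 1,
                                   n_realizations = 25, max_neighbors = 25) {
  methods <- c("idw", "pso-idw", "ga-idw", "gs-idw", "ok", "sgcs")
  if (!method %in% methods)
    stop_schema("unknown interpolation method '%s'", method)
  n <- nrow(footprints)
  if (n < 10) stop("need >= 10 footprints")
  z <- footprints[[metric]]
  if (is.null(z)) stop_schema("metric column '%s' absent", metric)
  idx <- with_seed(derive_seed(seed, "split"),
                   sample.int(n, round(split_frac * n)))
  tr <- footprints[idx, ]; te <- footprints[-idx, ]
  ztr <- tr[[metric]]; zte <- te[[metric]]
  need_model <- method %in% c("ok", "sgcs")
  if (need_model && is.null(model)) {
    ev <- empirical_variogram(tr$x, tr$y, ztr)
    model <- fit_variogram(ev)$best$model
  }
  pred <- switch(method,
    "idw" = idw(tr$x, tr$y, ztr, te[, c("x", "y")], beta = 2),
    "pso-idw" = ,
    "ga-idw" = ,
    "gs-idw" = {
      mm <- c("pso-idw" = "pso", "ga-idw" = "ga", "gs-idw" = "grid")[[method]]
      opt <- optimize_beta(tr$x, tr$y, ztr,
                           idw_optimizer_config(mm, seed = seed))
      idw(tr$x, tr$y, ztr, te[, c("x", "y")], beta = opt$beta)
    },
    "ok" = ordinary_kriging(tr$x, tr$y, ztr, te[, c("x", "y")], model,
                            max_neighbors = max_neighbors)$estimates,
    "sgcs" = {
      if (is.null(grid)) stop("sgcs evaluation needs a grid")
      st <- sgcs(tr$x, tr$y, ztr, grid, model,
                 n_realizations = n_realizations, seed = seed,
                 max_neighbors = min(max_neighbors, 16))
      raster_at(realization_mean(st), te$x, te$y)
    })
  ok <- is.finite(pred) & is.finite(zte)
  r2 <- r_squared(zte[ok], pred[ok])
  structure(list(metric = metric, method = method, r2_test = r2,
                 n_train = nrow(tr), n_test = nrow(te),
                 retained = is.finite(r2) && r2 >= threshold,
                 threshold = threshold),
            class = "cs_interp_report")
}

#' Apply the retention gate to a set of test R-squared values
#' @param r2 Named numeric vector of hold-out R^2 values.
#' @param threshold Gate (default 0.5, inclusive).
#' @return Names of the retained variables.
#' @export
retention_gate <- function(r2, threshold = 0.5) {
  names(r2)[!is.na(r2) & r2 >= threshold]
}
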