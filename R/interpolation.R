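# Spatial interpolation of point soil surveys on projected metre
# coordinates, and model selection by leave-one-out cross-validated RMSE.
# Fifteen candidate interpolators are supported: IDW with powers 1-3;
# thin-plate, completely regularized and tension radial-basis splines; and
# ordinary / simple / universal kriging, each with gaussian, spherical or
# exponential semivariogram models.

#' Construct an interpolator specification
#'
#' @param family `"IDW"`, `"RBF"` or `"Kriging"`.
#' @param variant for IDW: `"power1"`, `"power2"`, `"power3"`; for RBF:
#'   `"TPS"`, `"CRS"`, `"ST"`; for Kriging: `"<method>_<model>"` with
#'   method in ordinary/simple/universal and model in
#'   gaussian/spherical/exponential.
#' @param params optional list of variant-specific settings: `power`
#'   (IDW), `width` (CRS/ST kernel scale, default mean nearest-neighbour
#'   distance), `mean` (simple kriging known mean, default sample mean),
#'   `nbins`/`nugget_floor` (variogram fitting).
#' @return an `interpolator_spec`.
#' @export
interpolator_spec <- function(family = c("IDW", "RBF", "Kriging"),
                              variant, params = list()) {
  family <- match.arg(family)
  ok <- switch(family,
    IDW = c("power1", "power2", "power3"),
    RBF = c("TPS", "CRS", "ST"),
    Kriging = as.vector(outer(c("ordinary", "simple", "universal"),
                              c("gaussian", "spherical", "exponential"),
                              paste, sep = "_")))
  if (!variant %in% ok)
    stop(sprintf("unknown %s variant '%s'", family, variant), call. = FALSE)
  structure(list(family = family, variant = variant, params = params),
            class = "interpolator_spec")
}

#' The fifteen candidate interpolators in canonical order
#'
#' Order: IDW powers 1-3, then TPS, CRS, ST, then kriging
#' ordinary/simple/universal each with gaussian, spherical, exponential
#' models. This order is also the deterministic tie-break in
#' [select_best()].
#'
#' @param params optional shared params list passed to every spec.
#' @return list of 15 `interpolator_spec`s.
#' @export
candidate_interpolators <- function(params = list()) {
  specs <- c(
    lapply(paste0("power", 1:3), function(v)
      interpolator_spec("IDW", v, params)),
    lapply(c("TPS", "CRS", "ST"), function(v)
      interpolator_spec("RBF", v, params)),
    lapply(as.vector(t(outer(c("ordinary", "simple", "universal"),
                             c("gaussian", "spherical", "exponential"),
                             paste, sep = "_"))), function(v)
      interpolator_spec("Kriging", v, params)))
  names(specs) <- vapply(specs, function(s)
    paste(s$family, s$variant, sep = "_"), character(1))
  specs
}

#' @export
print.interpolator_spec <- function(x, ...) {
  cat(sprintf("interpolator_spec: %s / %s\n", x$family, x$variant))
  invisible(x)
}

.check_points <- function(points, parameter) {
  if (!all(c("x", "y") %in% names(points)))
    stop("sample table needs x and y columns", call. = FALSE)
  if (!parameter %in% names(points))
    stop("parameter '", parameter, "' not found in samples", call. = FALSE)
  keep <- is.finite(points$x) & is.finite(points$y) &
    is.finite(points[[parameter]])
  pts <- points[keep, c("x", "y", parameter)]
  if (nrow(pts) < 1)
    stop("no finite samples for parameter '", parameter, "'", call. = FALSE)
  pts
}

.pairwise_dist <- function(x1, y1, x2 = x1, y2 = y1) {
  dx <- outer(x1, x2, "-")
  dy <- outer(y1, y2, "-")
  sqrt(dx * dx + dy * dy)
}

.check_duplicates <- function(pts) {
  d <- .pairwise_dist(pts$x, pts$y)
  d[upper.tri(d, diag = TRUE)] <- Inf
  if (any(d < 1e-9)) {
    ij <- which(d < 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "duplicate sample locations (points %d and %d coincide within 1e-9 m)",
      ij[2], ij[1]), call. = FALSE)
  }
}

.mean_nn_dist <- function(pts) {
  d <- .pairwise_dist(pts$x, pts$y)
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# ---- IDW --------------------------------------------------------------

.predict_idw <- function(pts, z, qx, qy, power) {
  d <- .pairwise_dist(qx, qy, pts$x, pts$y)
  out <- numeric(length(qx))
  exact <- d < 1e-9
  hit <- rowSums(exact) > 0
  if (any(hit))
    out[hit] <- z[apply(exact[hit, , drop = FALSE], 1, which.max)]
  if (any(!hit)) {
    w <- d[!hit, , drop = FALSE]^(-power)
    out[!hit] <- as.numeric(w %*% z) / rowSums(w)
  }
  out
}

# ---- RBF splines ------------------------------------------------------

# Kernel functions; all are 0 at r = 0. TPS is augmented with a full
# linear polynomial; CRS and ST (whose kernels decay) with a constant.
.rbf_kernel <- function(r, variant, width) {
  euler <- 0.5772156649015329
  if (variant == "TPS") {
    k <- r * r * log(r)
    k[r == 0] <- 0
    return(k)
  }
  if (variant == "CRS") {
    tau <- width
    s <- r / tau
    k <- (r^2 / 4) * (log(r / (2 * tau)) + euler - 1) +
      tau^2 * (besselK(s, 0) + euler + log(r / (2 * tau)))
    k <- k / (2 * pi)
    k[r == 0] <- 0
    return(k)
  }
  if (variant == "ST") {
    phi <- 1 / width
    k <- -(log(r * phi / 2) + euler + besselK(r * phi, 0)) /
      (2 * pi * phi^2)
    k[r == 0] <- 0
    return(k)
  }
  stop("unknown RBF variant", call. = FALSE)
}

.fit_rbf <- function(pts, z, variant, width) {
  .check_duplicates(pts)
  n <- nrow(pts)
  # center coordinates: conditions the polynomial block and makes the
  # fit exactly translation-invariant
  cx <- mean(pts$x)
  cy <- mean(pts$y)
  K <- .rbf_kernel(.pairwise_dist(pts$x, pts$y), variant, width)
  P <- if (variant == "TPS") cbind(1, pts$x - cx, pts$y - cy)
       else matrix(1, n, 1)
  m <- ncol(P)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, m, m)))
  rhs <- c(z, rep(0, m))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular RBF system (near-duplicate or degenerate points): ",
         conditionMessage(e), call. = FALSE))
  list(alpha = sol[1:n], beta = sol[(n + 1):(n + m)],
       variant = variant, width = width, pts = pts, cx = cx, cy = cy)
}

.predict_rbf <- function(fit, z, qx, qy) {
  d <- .pairwise_dist(qx, qy, fit$pts$x, fit$pts$y)
  K <- .rbf_kernel(d, fit$variant, fit$width)
  P <- if (fit$variant == "TPS") cbind(1, qx - fit$cx, qy - fit$cy)
       else matrix(1, length(qx), 1)
  out <- as.numeric(K %*% fit$alpha + P %*% fit$beta)
  # exactness at coincident query points regardless of conditioning
  exact <- d < 1e-9
  hit <- rowSums(exact) > 0
  if (any(hit))
    out[hit] <- z[apply(exact[hit, , drop = FALSE], 1, which.max)]
  out
}

# ---- Variogram + kriging ---------------------------------------------

.vgm_value <- function(h, model, nugget, psill, range) {
  g <- switch(model,
    exponential = 1 - exp(-3 * h / range),
    gaussian = 1 - exp(-3 * (h / range)^2),
    spherical = ifelse(h < range,
                       1.5 * h / range - 0.5 * (h / range)^3, 1),
    stop("unknown variogram model", call. = FALSE))
  out <- nugget + psill * g
  out[h == 0] <- 0
  out
}

#' Empirical semivariogram of a point sample
#'
#' Distance-binned method-of-moments estimator: pairs are grouped into
#' `nbins` equal-width distance classes up to `maxdist` (default half the
#' maximum pairwise distance) and gamma is half the mean squared value
#' difference per class.
#'
#' @param points sample table with `x`, `y` columns.
#' @param parameter column to analyse.
#' @param nbins number of distance classes (default 12).
#' @param maxdist maximum pair distance used (default half the max).
#' @return data.frame with `dist` (mean pair distance), `gamma`, `n`
#'   (pair count) per non-empty bin.
#' @export
empirical_variogram <- function(points, parameter, nbins = 12,
                                maxdist = NULL) {
  pts <- .check_points(points, parameter)
  z <- pts[[parameter]]
  d <- .pairwise_dist(pts$x, pts$y)
  sq <- 0.5 * outer(z, z, "-")^2
  keep <- upper.tri(d)
  d <- d[keep]
  sq <- sq[keep]
  if (is.null(maxdist)) maxdist <- max(d) / 2
  inr <- d > 0 & d <= maxdist
  d <- d[inr]
  sq <- sq[inr]
  if (!length(d)) stop("no point pairs within maxdist", call. = FALSE)
  bin <- pmin(ceiling(d / (maxdist / nbins)), nbins)
  out <- data.frame(
    dist = as.numeric(tapply(d, bin, mean)),
    gamma = as.numeric(tapply(sq, bin, mean)),
    n = as.integer(table(bin)))
  out[order(out$dist), , drop = FALSE]
}

#' Fit a semivariogram model by weighted least squares
#'
#' Weights are the per-bin pair counts; the nugget is floored at 0.
#' Deterministic initialisation (nugget 0, partial sill = variance of the
#' data implied by the empirical gamma, range a third of the largest bin
#' distance).
#'
#' @param ev empirical variogram from [empirical_variogram()].
#' @param model `"gaussian"`, `"spherical"` or `"exponential"`.
#' @return list with `model`, `nugget`, `psill`, `range`.
#' @export
fit_variogram <- function(ev, model = c("exponential", "spherical",
                                        "gaussian")) {
  model <- match.arg(model)
  smax <- max(ev$gamma)
  dmax <- max(ev$dist)
  obj <- function(p) {
    g <- .vgm_value(ev$dist, model, p[1], p[2], p[3])
    sum(ev$n * (ev$gamma - g)^2)
  }
  fit <- stats::optim(c(0, smax, dmax / 3), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-10 * max(smax, 1e-12), dmax * 1e-3),
                      upper = c(smax * 2 + 1e-12, smax * 4 + 1e-12,
                                dmax * 10))
  list(model = model, nugget = fit$par[1], psill = fit$par[2],
       range = fit$par[3])
}

.krige_fit <- function(pts, z, variant, params) {
  .check_duplicates(pts)
  if (nrow(pts) < 10)
    stop("kriging needs at least 10 points for variogram fitting",
         call. = FALSE)
  method <- sub("_.*$", "", variant)
  model <- sub("^.*_", "", variant)
  vg <- params$variogram
  if (is.null(vg)) {
    df <- data.frame(x = pts$x, y = pts$y, z = z)
    ev <- empirical_variogram(df, "z", nbins = params$nbins %||% 12)
    vg <- fit_variogram(ev, model)
  }
  sill <- vg$nugget + vg$psill
  if (sill <= 0) sill <- stats::var(z) + 1e-12
  C <- sill - .vgm_value(.pairwise_dist(pts$x, pts$y), model,
                         vg$nugget, vg$psill, vg$range)
  n <- nrow(pts)
  if (method == "ordinary") {
    A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  } else if (method == "universal") {
    F <- cbind(1, pts$x - mean(pts$x), pts$y - mean(pts$y))
    A <- rbind(cbind(C, F), cbind(t(F), matrix(0, 3, 3)))
  } else {
    A <- C + diag(1e-10 * sill, n)
  }
  list(method = method, model = model, vg = vg, sill = sill, A = A,
       pts = pts, z = z, n = n,
       mean = params$mean %||% mean(z),
       cx = mean(pts$x), cy = mean(pts$y))
}

.krige_predict <- function(fit, qx, qy) {
  d <- .pairwise_dist(qx, qy, fit$pts$x, fit$pts$y)
  c0 <- fit$sill - .vgm_value(d, fit$model, fit$vg$nugget, fit$vg$psill,
                              fit$vg$range)
  n <- fit$n
  m <- length(qx)
  rhs <- switch(fit$method,
    ordinary = rbind(t(c0), rep(1, m)),
    universal = rbind(t(c0), rep(1, m), qx - fit$cx, qy - fit$cy),
    simple = t(c0))
  sol <- tryCatch(solve(fit$A, rhs), error = function(e)
    stop("singular kriging system: ", conditionMessage(e), call. = FALSE))
  lambda <- sol[1:n, , drop = FALSE]
  out <- if (fit$method == "simple")
    fit$mean + as.numeric(crossprod(lambda, fit$z - fit$mean))
  else as.numeric(crossprod(lambda, fit$z))
  exact <- d < 1e-9
  hit <- rowSums(exact) > 0
  if (any(hit))
    out[hit] <- fit$z[apply(exact[hit, , drop = FALSE], 1, which.max)]
  out
}

# ---- Public prediction API -------------------------------------------

#' Predict a soil parameter at query locations
#'
#' All interpolators are exact: a query coinciding with a sample location
#' (within 1e-9 m) returns the measured value. IDW is a global
#' distance-decay weighted mean; the RBF splines solve the radial-basis
#' linear system for their kernel; the kriging variants fit an empirical
#' semivariogram by weighted least squares and solve the corresponding
#' kriging system.
#'
#' @param spec an `interpolator_spec`.
#' @param points sample table with `x`, `y` and the parameter column.
#' @param parameter name of the column to interpolate.
#' @param query data.frame (or list) with `x` and `y` of query locations.
#' @return numeric vector of predictions, one per query row.
#' @export
predict_surface <- function(spec, points, parameter, query) {
  pts <- .check_points(points, parameter)
  z <- pts[[parameter]]
  qx <- as.numeric(query$x)
  qy <- as.numeric(query$y)
  stopifnot(length(qx) == length(qy), length(qx) >= 1)
  if (spec$family == "IDW") {
    power <- spec$params$power %||% as.integer(sub("power", "", spec$variant))
    return(.predict_idw(pts, z, qx, qy, power))
  }
  if (nrow(pts) == 1) return(rep(z, length(qx)))
  if (spec$family == "RBF") {
    width <- spec$params$width %||% .mean_nn_dist(pts)
    fit <- .fit_rbf(pts, z, spec$variant, width)
    return(.predict_rbf(fit, z, qx, qy))
  }
  fit <- .krige_fit(pts, z, spec$variant, spec$params)
  .krige_predict(fit, qx, qy)
}

#' Leave-one-out cross-validated RMSE of an interpolator
#'
#' Each sample point is withheld in turn, the interpolator is refitted on
#' the remainder and the withheld value predicted. RMSE is the square
#' root of the mean squared residual. For kriging the semivariogram model
#' is fitted once on the full sample and held fixed across folds -- the
#' convention of geostatistical cross-validation suites -- while the
#' kriging system itself is re-solved per fold.
#'
#' @inheritParams predict_surface
#' @return a `cv_result`: list with `spec`, `rmse`, `n`, `residuals`
#'   (predicted minus measured, in sample order) and `valid`.
#' @export
loocv_rmse <- function(spec, points, parameter) {
  pts <- .check_points(points, parameter)
  n <- nrow(pts)
  if (n < 3) stop("LOOCV needs at least 3 points", call. = FALSE)
  if (spec$family == "Kriging" && is.null(spec$params$variogram)) {
    if (n < 10)
      stop("kriging needs at least 10 points for variogram fitting",
           call. = FALSE)
    .check_duplicates(pts)
    ev <- empirical_variogram(pts, parameter,
                              nbins = spec$params$nbins %||% 12)
    spec$params$variogram <- fit_variogram(ev, sub("^.*_", "",
                                                   spec$variant))
  }
  res <- numeric(n)
  for (i in seq_len(n)) {
    pred <- tryCatch(
      predict_surface(spec, pts[-i, , drop = FALSE], parameter,
                      list(x = pts$x[i], y = pts$y[i])),
      error = function(e)
        stop(sprintf("LOOCV fold %d failed: %s", i, conditionMessage(e)),
             call. = FALSE))
    res[i] <- pred - pts[[parameter]][i]
  }
  structure(list(spec = spec, rmse = sqrt(mean(res^2)), n = n,
                 residuals = res, valid = TRUE),
            class = "cv_result")
}

#' Select the best interpolator by LOOCV RMSE
#'
#' Evaluates every candidate; candidates whose cross-validation fails are
#' marked invalid and skipped. Ties are broken by candidate order, which
#' for [candidate_interpolators()] is the canonical IDW, RBF, kriging
#' enumeration.
#'
#' @inheritParams predict_surface
#' @param candidates list of `interpolator_spec`s (default all 15).
#' @return list with `best` (the winning spec), `best_rmse`, `results`
#'   (per-candidate `cv_result` or error message) and `leaderboard`
#'   (data.frame: family, variant, rmse, valid).
#' @export
select_best <- function(points, parameter,
                        candidates = candidate_interpolators()) {
  stopifnot(length(candidates) >= 1)
  results <- lapply(candidates, function(sp)
    tryCatch(loocv_rmse(sp, points, parameter),
             error = function(e) structure(
               list(spec = sp, rmse = NA_real_, n = NA_integer_,
                    residuals = NULL, valid = FALSE,
                    error = conditionMessage(e)),
               class = "cv_result")))
  rmse <- vapply(results, `[[`, numeric(1), "rmse")
  valid <- vapply(results, `[[`, logical(1), "valid")
  if (!any(valid)) stop("all interpolation candidates failed LOOCV",
                        call. = FALSE)
  best_i <- which(valid)[which.min(rmse[valid])]
  leaderboard <- data.frame(
    family = vapply(candidates, `[[`, character(1), "family"),
    variant = vapply(candidates, `[[`, character(1), "variant"),
    rmse = rmse, valid = valid, row.names = NULL)
  list(best = candidates[[best_i]], best_rmse = unname(rmse[best_i]),
       results = results, leaderboard = leaderboard)
}

#' Interpolate a parameter onto a raster grid
#'
#' Predicts at cell centres over the given extent. Optionally, cells
#' farther than `hull_buffer` metres outside the convex hull of the
#' samples are set to no-data (`NA`); by default no hull masking is done.
#'
#' @inheritParams predict_surface
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cellsize cell edge (m).
#' @param hull_buffer optional buffer distance (m) around the sample
#'   convex hull beyond which cells become no-data; `NULL` disables.
#' @param cell_cap guard against runaway grids (default 4e6 cells).
#' @param crs_tag free-text CRS note for the output raster.
#' @return a `raster_grid` of predictions.
#' @export
rasterize_surface <- function(spec, points, parameter, extent, cellsize,
                              hull_buffer = NULL, cell_cap = 4e6,
                              crs_tag = "") {
  stopifnot(length(extent) == 4, extent[2] > extent[1],
            extent[4] > extent[3], cellsize > 0)
  nc <- max(1L, ceiling((extent[2] - extent[1]) / cellsize - 1e-9))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / cellsize - 1e-9))
  if (as.double(nr) * nc > cell_cap)
    stop(sprintf("grid of %d x %d cells exceeds cell cap %g", nr, nc,
                 cell_cap), call. = FALSE)
  grid <- raster_grid(matrix(NA_real_, nr, nc), extent[1], extent[3],
                      cellsize, crs_tag = crs_tag)
  cc <- raster_cell_centers(grid)
  pred <- predict_surface(spec, points, parameter, cc)
  if (!is.null(hull_buffer)) {
    pts <- .check_points(points, parameter)
    hull <- grDevices::chull(pts$x, pts$y)
    px <- pts$x[hull]
    py <- pts$y[hull]
    inside <- .point_in_poly(cc$x, cc$y, px, py)
    near <- .dist_to_poly(cc$x, cc$y, px, py) <= hull_buffer
    pred[!(inside | near)] <- NA_real_
  }
  grid$values <- matrix(pred, nr, nc, byrow = TRUE)
  grid
}

# Ray-casting point-in-polygon for a single ring (planar coordinates).
.point_in_poly <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Distance from points to a polygon boundary (min over edges).
.dist_to_poly <- function(x, y, px, py) {
  n <- length(px)
  d2 <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ex <- px[i] - px[j]
    ey <- py[i] - py[j]
    len2 <- ex * ex + ey * ey
    t <- if (len2 > 0) pmin(pmax(((x - px[j]) * ex + (y - py[j]) * ey) /
                                   len2, 0), 1) else 0
    dx <- x - (px[j] + t * ex)
    dy <- y - (py[j] + t * ey)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}
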