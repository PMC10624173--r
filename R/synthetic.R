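# Seeded synthetic soil surveys: stationary Gaussian random fields with
# exponential covariance (simulated by circulant embedding), transformed
# cell-wise to prescribed marginal moments (mean, SD, skewness) and
# clipped to the observed parameter range; sampled on a regular survey
# grid; plus an SQI-linked yield simulator. Together these emulate the
# statistical signature of a semi-arid 4,200-ha survey sampled on a
# 400 m grid (~260 points), so the whole pipeline is testable without
# field data.

#' Default marginal catalog for the 24 soil indicators
#'
#' Descriptive statistics (min, max, mean, SD, skewness, in parameter
#' units) characterising surface soils (0-30 cm) of the emulated
#' semi-arid survey area.
#'
#' @return data.frame with columns `name`, `min`, `max`, `mean`, `sd`,
#'   `skewness`.
#' @export
default_marginals <- function() {
  tab <- rbind(
    c("Clay", 10.53, 60.83, 28.62, 7.44, 0.41),
    c("Silt", 10.54, 44.95, 24.65, 6.42, 0.21),
    c("Sand", 10.54, 76.80, 46.73, 11.98, -0.87),
    c("HC", 0.02, 18.75, 1.57, 2.57, 3.58),
    c("BD", 0.95, 1.87, 1.49, 0.16, -0.69),
    c("AWC", 2.69, 18.59, 11.10, 2.60, -0.53),
    c("Slope", 1, 30, 5.10, 6.89, 2.17),
    c("Depth", 20, 120, 74.46, 38.53, -0.29),
    c("pH", 7.09, 9.82, 8.27, 0.38, -0.50),
    c("EC", 0.042, 1.267, 0.19, 0.19, 3.84),
    c("OM", 0.54, 4.04, 1.65, 0.82, 0.96),
    c("CaCO3", 1.23, 43.67, 11.24, 9.08, 1.26),
    c("CEC", 9.63, 47.43, 30.03, 8.90, -0.31),
    c("ESP", 0.80, 11.49, 4.29, 1.83, 1.18),
    c("N", 0.036, 0.540, 0.140, 0.082, 1.56),
    c("P", 0.017, 24.16, 5.62, 2.47, 3.95),
    c("Ca", 7.17, 40.07, 25.14, 7.63, -0.39),
    c("Mg", 0.16, 10.39, 2.47, 2.03, 1.63),
    c("K", 0.29, 4.42, 1.19, 0.53, 1.70),
    c("Na", 0.15, 5.31, 1.24, 0.62, 2.72),
    c("Fe", 2.57, 77.83, 11.85, 9.41, 3.42),
    c("Zn", 0.16, 5.21, 0.61, 0.63, 3.77),
    c("Cu", 0.04, 5.65, 1.34, 0.77, 2.18),
    c("Mn", 4.78, 172.54, 33.95, 21.91, 2.77))
  out <- data.frame(name = tab[, 1],
                    min = as.numeric(tab[, 2]),
                    max = as.numeric(tab[, 3]),
                    mean = as.numeric(tab[, 4]),
                    sd = as.numeric(tab[, 5]),
                    skewness = as.numeric(tab[, 6]),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$sd > 0), all(out$min < out$max),
            all(out$mean >= out$min & out$mean <= out$max))
  out
}

#' Construct a synthetic field specification
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres; the default
#'   6.48 km square covers ~4,200 ha, which a 400 m sampling grid tiles
#'   with 256 points.
#' @param cellsize truth-raster cell edge (m), default 80.
#' @param corr_length exponential-covariance correlation length (m);
#'   default 800 m, twice the default sampling interval, so that
#'   interpolation is meaningfully better than the field mean.
#' @param seed integer RNG seed; fixed seed gives bit-identical fields.
#' @param marginals marginal catalog (default [default_marginals()]).
#' @return a `field_spec` list.
#' @export
field_spec <- function(extent = c(0, 6480, 0, 6480), cellsize = 80,
                       corr_length = 800, seed = 1,
                       marginals = default_marginals()) {
  stopifnot(length(extent) == 4, extent[2] > extent[1],
            extent[4] > extent[3], cellsize > 0, corr_length > 0)
  structure(list(extent = extent, cellsize = cellsize,
                 corr_length = corr_length, seed = as.integer(seed),
                 marginals = marginals),
            class = "field_spec")
}

# Standard-normal stationary field with exponential correlation, by
# circulant embedding on a doubled torus. Negative embedding eigenvalues
# (rare with this padding) are clamped to zero; the clamped mass is
# recorded on the result.
.grf_exponential <- function(nr, nc, cellsize, corr_length) {
  m1 <- 2L * nr
  m2 <- 2L * nc
  dx <- pmin(0:(m2 - 1), m2 - 0:(m2 - 1)) * cellsize
  dy <- pmin(0:(m1 - 1), m1 - 0:(m1 - 1)) * cellsize
  h <- sqrt(outer(dy^2, dx^2, "+"))
  C <- exp(-h / corr_length)
  lam <- Re(stats::fft(C))
  deficit <- sum(pmin(lam, 0)) / sum(abs(lam))
  lam <- pmax(lam, 0)
  eps <- matrix(complex(real = stats::rnorm(m1 * m2),
                        imaginary = stats::rnorm(m1 * m2)), m1, m2)
  Z <- stats::fft(sqrt(lam / (m1 * m2)) * eps)
  field <- Re(Z)[seq_len(nr), seq_len(nc), drop = FALSE]
  attr(field, "eigen_deficit") <- deficit
  field
}

# Solve the shifted-lognormal shape from a target skewness:
# skew = (w + 2) * sqrt(w - 1) with w = exp(sigma^2).
.lognormal_w <- function(skew) {
  g2 <- skew^2
  f <- function(w) (w + 2)^2 * (w - 1) - g2
  stats::uniroot(f, c(1 + 1e-12, 1e3), tol = 1e-14)$root
}

#' Generate one synthetic parameter field
#'
#' Draws a stationary standard-normal random field with exponential
#' covariance at the spec's correlation length, then transforms it
#' cell-wise to the parameter's marginal: an affine map to (mean, SD)
#' for near-symmetric marginals (`|skewness| < 0.05`), otherwise a
#' moment-matched shifted lognormal (reflected for negative skew), so
#' that even mildly skewed indicators reproduce the sign and size of
#' their skewness. Values are finally clipped to the
#' marginal's `[min, max]`; the clipped fraction is recorded in the
#' `clipped_frac` attribute.
#'
#' @param spec a `field_spec`.
#' @param parameter marginal name to simulate.
#' @return a `raster_grid` with attributes `parameter` and
#'   `clipped_frac`.
#' @export
generate_field <- function(spec, parameter) {
  m <- spec$marginals[spec$marginals$name == parameter, ]
  if (nrow(m) != 1)
    stop("no marginal spec for parameter '", parameter, "'", call. = FALSE)
  nr <- max(1L, round((spec$extent[4] - spec$extent[3]) / spec$cellsize))
  nc <- max(1L, round((spec$extent[2] - spec$extent[1]) / spec$cellsize))
  idx <- match(parameter, spec$marginals$name)
  set.seed(spec$seed + 101L * idx)
  z <- .grf_exponential(nr, nc, spec$cellsize, spec$corr_length)
  if (abs(m$skewness) < 0.05) {
    x <- m$mean + m$sd * z
  } else {
    w <- .lognormal_w(abs(m$skewness))
    sigma <- sqrt(log(w))
    emu <- m$sd / sqrt(w * (w - 1))
    theta <- m$mean - emu * sqrt(w)
    ln <- theta + emu * exp(sigma * z)
    x <- if (m$skewness > 0) ln else 2 * m$mean - ln
  }
  clipped <- mean(x < m$min | x > m$max)
  x <- pmin(pmax(x, m$min), m$max)
  out <- raster_grid(x, spec$extent[1], spec$extent[3], spec$cellsize)
  attr(out, "parameter") <- parameter
  attr(out, "clipped_frac") <- clipped
  out
}

#' Sample synthetic fields on a survey grid
#'
#' Reads each field at the nodes of a regular grid (spacing in metres,
#' nodes offset half a spacing from the extent edge), with optional
#' uniform positional jitter. All fields must share geometry.
#'
#' @param fields named list of `raster_grid`s (one per parameter).
#' @param spacing grid interval (m), default 400.
#' @param jitter max absolute positional jitter (m), default 0.
#' @param seed RNG seed for the jitter.
#' @return a `sample_table` data.frame: `id`, `x`, `y`, one column per
#'   field.
#' @export
sample_grid <- function(fields, spacing = 400, jitter = 0, seed = 1) {
  stopifnot(length(fields) >= 1, spacing > 0)
  ref <- fields[[1]]
  for (f in fields)
    if (!all(dim(f$values) == dim(ref$values)) ||
        f$cellsize != ref$cellsize || f$xll != ref$xll || f$yll != ref$yll)
      stop("fields do not share geometry", call. = FALSE)
  nr <- nrow(ref$values)
  nc <- ncol(ref$values)
  width <- nc * ref$cellsize
  height <- nr * ref$cellsize
  if (spacing > width || spacing > height)
    stop("spacing exceeds field extent", call. = FALSE)
  xs <- seq(ref$xll + spacing / 2, ref$xll + width - 1e-9, by = spacing)
  ys <- seq(ref$yll + spacing / 2, ref$yll + height - 1e-9, by = spacing)
  pts <- expand.grid(x = xs, y = ys)
  set.seed(seed)
  if (jitter > 0) {
    pts$x <- pts$x + stats::runif(nrow(pts), -jitter, jitter)
    pts$y <- pts$y + stats::runif(nrow(pts), -jitter, jitter)
    pts$x <- pmin(pmax(pts$x, ref$xll), ref$xll + width - 1e-9)
    pts$y <- pmin(pmax(pts$y, ref$yll), ref$yll + height - 1e-9)
  }
  out <- data.frame(id = seq_len(nrow(pts)), x = pts$x, y = pts$y)
  col <- pmin(pmax(floor((pts$x - ref$xll) / ref$cellsize) + 1, 1), nc)
  row <- pmin(pmax(nr - floor((pts$y - ref$yll) / ref$cellsize), 1), nr)
  for (nm in names(fields))
    out[[nm]] <- fields[[nm]]$values[cbind(row, col)]
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Simulate SQI-linked yields
#'
#' `yield = base + gain * sqi + N(0, noise_sd)`, floored at `min_yield`.
#' When `base`, `gain` or `noise_sd` are `NULL` they are solved from the
#' supplied SQI values so that yields span roughly `yield_range` with
#' mean `yield_mean`, and the population R-squared of yield on SQI equals
#' `target_r2` (via the variance decomposition
#' `r2 = gain^2 var(sqi) / (gain^2 var(sqi) + noise_sd^2)`).
#'
#' @param sqi numeric vector of SQI values in `[0.1, 1]`.
#' @param base intercept (kg ha-1), or `NULL` to solve.
#' @param gain slope (kg ha-1 per SQI unit), or `NULL` to solve.
#' @param noise_sd Gaussian noise SD (kg ha-1), or `NULL` to solve.
#' @param seed RNG seed.
#' @param yield_range,yield_mean targets for the solved defaults
#'   (defaults 900-3000 and 1600 kg ha-1).
#' @param target_r2 population R-squared target for the solved defaults
#'   (default 0.67).
#' @param min_yield floor applied after adding noise (default 1).
#' @return numeric yields (kg ha-1) with attributes `base`, `gain`,
#'   `noise_sd`.
#' @export
simulate_yield <- function(sqi, base = NULL, gain = NULL, noise_sd = NULL,
                           seed = 1, yield_range = c(900, 3000),
                           yield_mean = 1600, target_r2 = 0.67,
                           min_yield = 1) {
  stopifnot(length(sqi) >= 2, all(is.finite(sqi)))
  s_sd <- stats::sd(sqi)
  if (is.null(gain)) {
    if (s_sd == 0) stop("constant SQI: cannot solve default gain",
                        call. = FALSE)
    total_sd <- diff(yield_range) / 4.5
    gain <- total_sd * sqrt(target_r2) / s_sd
  }
  if (is.null(base)) base <- yield_mean - gain * mean(sqi)
  if (is.null(noise_sd)) {
    noise_sd <- if (target_r2 >= 1 || s_sd == 0) 0
                else abs(gain) * s_sd * sqrt(1 / target_r2 - 1)
  }
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  y <- base + gain * sqi + stats::rnorm(length(sqi), 0, noise_sd)
  y <- pmax(y, min_yield)
  attr(y, "base") <- base
  attr(y, "gain") <- gain
  attr(y, "noise_sd") <- noise_sd
  y
}

#' Generate a complete synthetic soil survey
#'
#' Simulates a truth raster for every catalog parameter, samples them on
#' the survey grid and returns both, plus a manifest (seed, geometry,
#' correlation length, per-parameter clipped fractions) sufficient to
#' reproduce the survey bit-identically.
#'
#' @param seed integer seed driving all randomness.
#' @param spec a `field_spec`; its own seed is overridden by `seed`.
#' @param spacing,jitter survey-grid sampling controls, see
#'   [sample_grid()].
#' @param parameters which marginals to simulate (default: all).
#' @return list with `samples` (a `sample_table`), `fields` (named
#'   `raster_grid` list) and `manifest`.
#' @export
synthetic_survey <- function(seed = 1, spec = field_spec(seed = seed),
                             spacing = 400, jitter = 0,
                             parameters = spec$marginals$name) {
  spec$seed <- as.integer(seed)
  fields <- lapply(parameters, function(p) generate_field(spec, p))
  names(fields) <- parameters
  samples <- sample_grid(fields, spacing = spacing, jitter = jitter,
                         seed = seed)
  manifest <- list(
    seed = spec$seed, extent = spec$extent, cellsize = spec$cellsize,
    corr_length = spec$corr_length, spacing = spacing, jitter = jitter,
    n_points = nrow(samples),
    clipped_frac = stats::setNames(
      vapply(fields, function(f) attr(f, "clipped_frac"), numeric(1)),
      parameters))
  list(samples = samples, fields = fields, manifest = manifest)
}
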