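test_that("IDW reduces to known closed forms on tiny configurations", {
  # single sample: constant surface
  one <- data.frame(id = 1, x = 0, y = 0, z = 7)
  sp <- interpolator_spec("IDW", "power2")
  expect_equal(predict_surface(sp, one, "z",
                               list(x = c(5, -3), y = c(2, 9))),
               c(7, 7))
  # unit-square corners, values 0,0,1,1: centre is the plain mean
  sq <- data.frame(id = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                   z = c(0, 0, 1, 1))
  expect_equal(predict_surface(sp, sq, "z", list(x = 0.5, y = 0.5)), 0.5,
               tolerance = 1e-12)
  # exactness at sample locations
  expect_equal(predict_surface(sp, sq, "z", sq[, c("x", "y")]), sq$z)
})

test_that("all interpolator families are exact at sample locations", {
  pts <- toy_points(n = 15, seed = 2)
  for (nm in c("IDW_power1", "IDW_power3", "RBF_TPS", "RBF_CRS",
               "RBF_ST")) {
    sp <- candidate_interpolators()[[nm]]
    expect_equal(predict_surface(sp, pts, "z", pts[, c("x", "y")]),
                 pts$z, tolerance = 1e-6, label = nm)
  }
  # kriging needs >= 10 points
  for (nm in c("Kriging_ordinary_exponential", "Kriging_simple_spherical",
               "Kriging_universal_gaussian")) {
    sp <- candidate_interpolators()[[nm]]
    expect_equal(predict_surface(sp, pts, "z", pts[, c("x", "y")]),
                 pts$z, tolerance = 1e-6, label = nm)
  }
  expect_error(predict_surface(candidate_interpolators()[[7]],
                               pts[1:5, ], "z",
                               list(x = 1, y = 1)), "at least 10")
})

test_that("IDW predictions stay within the sample value range", {
  pts <- toy_points(n = 25, seed = 3)
  q <- expand.grid(x = seq(-200, 1200, by = 140),
                   y = seq(-200, 1200, by = 140))
  for (p in 1:3) {
    sp <- interpolator_spec("IDW", paste0("power", p))
    pred <- predict_surface(sp, pts, "z", q)
    expect_true(all(pred >= min(pts$z) - 1e-12 &
                      pred <= max(pts$z) + 1e-12))
  }
})

test_that("predictions are invariant to translating all coordinates", {
  pts <- toy_points(n = 20, seed = 4)
  q <- list(x = c(150, 420, 800), y = c(710, 80, 350))
  for (nm in c("IDW_power2", "RBF_TPS", "RBF_CRS", "RBF_ST",
               "Kriging_ordinary_exponential",
               "Kriging_universal_spherical")) {
    sp <- candidate_interpolators()[[nm]]
    base <- predict_surface(sp, pts, "z", q)
    shifted <- pts
    shifted$x <- shifted$x + 5000
    shifted$y <- shifted$y - 3000
    qs <- list(x = q$x + 5000, y = q$y - 3000)
    expect_equal(predict_surface(sp, shifted, "z", qs), base,
                 tolerance = 1e-7, label = nm)
  }
})

test_that("duplicate sample locations are reported with the pair", {
  pts <- data.frame(id = 1:12, x = c(1:11, 4), y = c(rep(2, 11), 2),
                    z = rnorm(12))
  expect_error(predict_surface(interpolator_spec("RBF", "TPS"), pts, "z",
                               list(x = 0, y = 0)),
               "duplicate.*4.*12|duplicate.*12.*4")
})

test_that("LOOCV matches an independent brute-force fold enumeration", {
  # 3 collinear points, values 0,1,2, IDW power 1: hand-checkable folds
  tri <- data.frame(id = 1:3, x = c(0, 1, 2), y = 0, z = c(0, 1, 2))
  cv <- loocv_rmse(interpolator_spec("IDW", "power1"), tri, "z")
  expect_equal(cv$rmse, bruteforce_idw_loocv(tri, 1), tolerance = 1e-12)
  expect_equal(cv$rmse, sqrt(32 / 27), tolerance = 1e-12)
  expect_equal(cv$residuals, c(4 / 3, 0, -4 / 3), tolerance = 1e-12)
  # random <= 5-point configurations, all IDW powers
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(3:5, 1)
    pts <- data.frame(id = 1:n, x = runif(n, 0, 100),
                      y = runif(n, 0, 100), z = rnorm(n))
    for (p in 1:3) {
      cv <- loocv_rmse(interpolator_spec("IDW", paste0("power", p)),
                       pts, "z")
      expect_equal(cv$rmse, bruteforce_idw_loocv(pts, p),
                   tolerance = 1e-9)
      # rmse^2 * n is exactly the residual sum of squares
      expect_equal(cv$rmse^2 * cv$n, sum(cv$residuals^2),
                   tolerance = 1e-12)
    }
  }
  # constant-valued points give zero RMSE under any method
  flat <- data.frame(id = 1:6, x = runif(6), y = runif(6), z = 2)
  expect_equal(loocv_rmse(interpolator_spec("RBF", "TPS"),
                          flat, "z")$rmse, 0, tolerance = 1e-9)
  expect_error(loocv_rmse(interpolator_spec("IDW", "power1"),
                          tri[1:2, ], "z"), "at least 3")
})

test_that("near-duplicated points leave IDW LOOCV essentially unchanged", {
  pts <- toy_points(n = 12, seed = 6)
  sp <- interpolator_spec("IDW", "power2")
  base <- loocv_rmse(sp, pts, "z")$rmse
  dup <- pts
  dup$x <- dup$x + 1e-6
  dup$id <- dup$id + 100
  both <- rbind(pts, dup)
  # with exact twins present, every withheld point is predicted by its twin
  expect_lt(loocv_rmse(sp, both, "z")$rmse, 1e-3)
  expect_gt(base, 1e-3)
})

test_that("select_best minimizes RMSE with first-minimum tie-break", {
  pts <- toy_points(n = 20, seed = 7)
  cand <- candidate_interpolators()[c("IDW_power1", "IDW_power2",
                                      "RBF_TPS")]
  sel <- select_best(pts, "z", cand)
  rmse <- sel$leaderboard$rmse
  expect_equal(sel$best_rmse, min(rmse, na.rm = TRUE))
  expect_identical(paste(sel$best$family, sel$best$variant, sep = "_"),
                   sel$leaderboard[which.min(rmse),
                                   c("family", "variant")] |>
                     unlist() |> paste(collapse = "_"))
  # single candidate returns itself
  solo <- select_best(pts, "z", cand["RBF_TPS"])
  expect_identical(solo$best$variant, "TPS")
  # constant data: every candidate ties at 0; first in order wins
  flat <- data.frame(id = 1:12, x = runif(12, 0, 100),
                     y = runif(12, 0, 100), z = 1)
  tie <- select_best(flat, "z", cand)
  expect_identical(tie$best$variant, "power1")
  # invalid candidates are skipped, not fatal
  few <- toy_points(n = 5, seed = 8)
  mix <- candidate_interpolators()[c("Kriging_ordinary_exponential",
                                     "IDW_power2")]
  sel2 <- select_best(few, "z", mix)
  expect_identical(sel2$best$family, "IDW")
  expect_false(sel2$leaderboard$valid[1])
})

test_that("on a smooth correlated field, geostatistical methods beat
           high-power IDW in most replicates", {
  wins <- 0L
  for (s in 1:20) {
    spec <- field_spec(extent = c(0, 2000, 0, 2000), cellsize = 100,
                       corr_length = 800, seed = s)
    f <- generate_field(spec, "Clay")
    pts <- sample_grid(list(Clay = f), spacing = 280, seed = s)
    ok <- loocv_rmse(interpolator_spec("Kriging", "ordinary_exponential"),
                     pts, "Clay")$rmse
    idw3 <- loocv_rmse(interpolator_spec("IDW", "power3"),
                       pts, "Clay")$rmse
    wins <- wins + (ok <= idw3)
  }
  expect_gte(wins, 16L)  # >= 80% of 20 seeded replicates
})

test_that("rasterize produces aligned grids and honours the cell cap", {
  pts <- toy_points(n = 10, seed = 9, extent = 100)
  sp <- interpolator_spec("IDW", "power2")
  # 1x1 grid: a single prediction at the cell centre
  r1 <- rasterize_surface(sp, pts, "z", c(0, 100, 0, 100), 100)
  expect_identical(dim(r1$values), c(1L, 1L))
  expect_equal(r1$values[1, 1],
               predict_surface(sp, pts, "z", list(x = 50, y = 50)))
  # constant samples: constant raster
  flat <- data.frame(id = 1:5, x = c(0, 20, 40, 60, 80), y = 10, z = 3)
  rf <- rasterize_surface(sp, flat, "z", c(0, 100, 0, 100), 25)
  expect_equal(rf$values, matrix(3, 4, 4), tolerance = 1e-12)
  # grid aligned to samples reproduces them exactly
  gridpts <- expand.grid(x = c(12.5, 37.5, 62.5, 87.5),
                         y = c(12.5, 37.5, 62.5, 87.5))
  gridpts$id <- seq_len(nrow(gridpts))
  set.seed(10)
  gridpts$z <- rnorm(nrow(gridpts))
  rg <- rasterize_surface(sp, gridpts, "z", c(0, 100, 0, 100), 25)
  cc <- raster_cell_centers(rg)
  pred <- as.vector(t(rg$values))
  idx <- match(paste(gridpts$x, gridpts$y), paste(cc$x, cc$y))
  expect_equal(pred[idx], gridpts$z)
  expect_error(rasterize_surface(sp, pts, "z", c(0, 1e6, 0, 1e6), 1),
               "cell cap")
  # hull masking: far-outside cells become no-data
  rh <- rasterize_surface(sp, pts, "z", c(-200, 300, -200, 300), 25,
                          hull_buffer = 10)
  expect_true(anyNA(rh$values))
  expect_false(all(is.na(rh$values)))
})

test_that("empirical variogram and WLS fit recover a known structure", {
  # white noise: flat variogram, fitted sill near the variance
  set.seed(12)
  n <- 120
  pts <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                    z = rnorm(n, 0, 2))
  ev <- empirical_variogram(pts, "z")
  expect_true(all(ev$n > 0))
  expect_equal(nrow(ev), 12)
  vg <- fit_variogram(ev, "exponential")
  expect_equal(vg$nugget + vg$psill, 4, tolerance = 1.5)
  # a smooth correlated field yields a rising variogram: gamma at short
  # range well below gamma at long range
  spec <- field_spec(extent = c(0, 2000, 0, 2000), cellsize = 50,
                     corr_length = 800, seed = 3)
  f <- generate_field(spec, "Clay")
  sp <- sample_grid(list(Clay = f), spacing = 120, seed = 3)
  ev2 <- empirical_variogram(sp, "Clay")
  expect_lt(ev2$gamma[1], 0.5 * max(ev2$gamma))
})
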