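test_that("compute_sqi is the weighted linear combination of scores", {
  w <- structure(c(A = 0.6, B = 0.4), class = "weight_vector")
  sc <- data.frame(id = 1:3, A = c(1, 0.1, 0.5), B = c(1, 0.1, 1.0))
  res <- compute_sqi(sc, w)
  expect_equal(res$sqi, c(1, 0.1, 0.6 * 0.5 + 0.4 * 1.0),
               tolerance = 1e-12)
  expect_equal(res$index100, 100 * res$sqi)
  expect_identical(res$class, c("S1", "N2", "S2"))
  expect_error(compute_sqi(data.frame(id = 1, Q = 1), w), "no overlap")
})

test_that("missing scores propagate unless renormalization is requested", {
  w <- structure(c(A = 0.5, B = 0.5), class = "weight_vector")
  sc <- data.frame(id = 1:2, A = c(0.4, NA), B = c(0.8, 0.8))
  strict <- compute_sqi(sc, w)
  expect_true(is.na(strict$sqi[2]))
  expect_false(attr(strict, "renormalized"))
  renorm <- compute_sqi(sc, w, renormalize = TRUE)
  expect_equal(renorm$sqi, c(0.6, 0.8), tolerance = 1e-12)
  expect_true(attr(renorm, "renormalized"))
  # missing weighted column: error unless renormalizing
  expect_error(compute_sqi(data.frame(id = 1, A = 0.5), w), "missing")
  one <- compute_sqi(data.frame(id = 1, A = 0.5), w, renormalize = TRUE)
  expect_equal(one$sqi, 0.5)
})

test_that("SQI is linear in the score table", {
  set.seed(31)
  w <- structure(c(A = 0.3, B = 0.5, C = 0.2), class = "weight_vector")
  s1 <- data.frame(id = 1:5, A = runif(5, 0.1, 1), B = runif(5, 0.1, 1),
                   C = runif(5, 0.1, 1))
  s2 <- data.frame(id = 1:5, A = runif(5, 0.1, 1), B = runif(5, 0.1, 1),
                   C = runif(5, 0.1, 1))
  for (t in c(0.25, 0.5, 0.8)) {
    mix <- s1
    for (p in c("A", "B", "C")) mix[[p]] <- t * s1[[p]] + (1 - t) * s2[[p]]
    expect_equal(compute_sqi(mix, w)$sqi,
                 t * compute_sqi(s1, w)$sqi +
                   (1 - t) * compute_sqi(s2, w)$sqi,
                 tolerance = 1e-12)
  }
  # improving any single score never lowers the SQI
  bump <- s1
  bump$B <- pmin(bump$B + 0.1, 1)
  expect_true(all(compute_sqi(bump, w)$sqi >= compute_sqi(s1, w)$sqi))
})

test_that("classification is total, exhaustive and uses the half-open
           upward convention", {
  expect_identical(classify_sqi(85), "S1")
  expect_identical(classify_sqi(100), "S1")
  expect_identical(classify_sqi(80), "S1")
  expect_identical(classify_sqi(60), "S2")
  expect_identical(classify_sqi(59.999), "S3")
  expect_identical(classify_sqi(50), "S3")
  expect_identical(classify_sqi(20), "N1")
  expect_identical(classify_sqi(19.999), "N2")
  expect_identical(classify_sqi(0), "N2")
  # total on a fine grid, and adjacent classes meet only at the break
  g <- seq(0, 100, by = 0.25)
  cls <- classify_sqi(g)
  expect_true(all(cls %in% c("S1", "S2", "S3", "N1", "N2")))
  expect_identical(rle(cls)$values, c("N2", "N1", "S3", "S2", "S1"))
  expect_error(classify_sqi(101), "outside")
  expect_error(classify_sqi(-0.5), "outside")
})

test_that("mask polygons claim exactly the cells whose centres they
           cover", {
  grid <- raster_grid(matrix(0.55, 10, 10), 0, 0, 10)
  # a square covering the 2x2 block of cell centres (15,15)-(25,25)
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(category = "settlement"),
    geometry = list(type = "Polygon", coordinates = list(list(
      list(12, 12), list(28, 12), list(28, 28), list(12, 28),
      list(12, 12)))))))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  masks <- read_geojson_masks(path)
  expect_identical(masks[[1]]$category, "settlement")
  cr <- mask_and_map(grid, masks)
  expect_identical(sum(cr$values == 10L), 4L)
  expect_identical(sum(cr$values == 3L), 96L)  # rest classified S3
  # empty mask set: pure classification
  cr0 <- mask_and_map(grid)
  expect_true(all(cr0$values == 3L))
  # mask covering the whole extent masks everything
  gj$features[[1]]$geometry$coordinates <-
    list(list(list(-1, -1), list(101, -1), list(101, 101), list(-1, 101),
              list(-1, -1)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  cr_all <- mask_and_map(grid, read_geojson_masks(path))
  expect_true(all(cr_all$values == 10L))
})

test_that("area tabulation conserves area and shares sum to 100", {
  # 10x10 raster of 100 m cells: each cell is 1 ha
  vals <- matrix(2L, 10, 10)
  vals[1:4, 1:10] <- 3L  # 40 cells S3
  grid <- raster_grid(vals, 0, 0, 100)
  attr(grid, "code_table") <- data.frame(code = 1:5,
                                         label = c("S1", "S2", "S3",
                                                   "N1", "N2"))
  at <- tabulate_areas(grid)
  expect_equal(at$area_ha[at$class == "S3"], 40)
  expect_equal(at$share_pct[at$class == "S3"], 40)
  expect_equal(sum(at$share_pct), 100, tolerance = 0.01)
  expect_equal(sum(at$area_ha), attr(at, "total_ha"))
  # uniform raster: one class at 100%
  uni <- raster_grid(matrix(2L, 5, 5), 0, 0, 100)
  at_uni <- tabulate_areas(uni)
  expect_equal(at_uni$share_pct, 100)
  # with NA (no-data) cells the classified area shrinks accordingly
  vals[1, 1] <- NA
  grid$values <- vals
  at2 <- tabulate_areas(grid)
  expect_equal(attr(at2, "total_ha"), 99)
  expect_equal(sum(at2$share_pct), 100, tolerance = 0.01)
  expect_error(tabulate_areas(raster_grid(matrix(NA_real_, 2, 2), 0, 0, 1)),
               "no classified")
})

test_that("raster scoring plus weighting equals per-point scoring on
           coincident samples", {
  sv <- synthetic_survey(seed = 13, spacing = 800,
                         parameters = c("OM", "Slope", "Depth"))
  catal <- default_threshold_catalog()
  catal <- catal[catal$name %in% c("OM", "Slope", "Depth"), ]
  w <- structure(c(OM = 0.5, Slope = 0.3, Depth = 0.2),
                 class = "weight_vector")
  score_rs <- lapply(stats::setNames(catal$name, catal$name), function(p) {
    i <- match(p, catal$name)
    score_raster(sv$fields[[p]], catal$direction[i], catal$lower[i],
                 catal$upper[i])
  })
  sqi_r <- compute_sqi_raster(score_rs, w)
  expect_true(all(sqi_r$values >= 0.1 - 1e-12 & sqi_r$values <= 1 + 1e-12))
  sc <- score_samples(sv$samples, catal)
  res <- compute_sqi(sc, w)
  # each sample carries the value of its containing truth cell
  cs <- sqi_r$cellsize
  col <- floor((sv$samples$x - sqi_r$xll) / cs) + 1
  row <- nrow(sqi_r$values) - floor((sv$samples$y - sqi_r$yll) / cs)
  expect_equal(sqi_r$values[cbind(row, col)], res$sqi, tolerance = 1e-9)
})
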