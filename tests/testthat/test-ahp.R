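test_that("pairwise matrix validation catches structural defects", {
  expect_error(pairwise_matrix(matrix(1, 2, 3)), "square")
  expect_error(pairwise_matrix(rbind(c(1, -2), c(-0.5, 1))), "non-positive")
  expect_error(pairwise_matrix(rbind(c(2, 1), c(1, 1))), "diagonal")
  # reciprocity: 2 * 0.4 != 1, offending indices reported
  expect_error(pairwise_matrix(rbind(c(1, 2), c(0.4, 1))),
               "reciprocity.*\\[2, 1\\]|reciprocity.*\\[1, 2\\]")
  # strict Saaty mode rejects off-scale ratios, permissive accepts
  m <- rbind(c(1, 2.5), c(1 / 2.5, 1))
  expect_error(pairwise_matrix(m, strict_saaty = TRUE), "Saaty")
  expect_s3_class(pairwise_matrix(m), "pairwise_matrix")
  # identity with unit diagonal is valid at any order
  expect_s3_class(pairwise_matrix(matrix(1, 4, 4), strict_saaty = TRUE),
                  "pairwise_matrix")
})

test_that("both weight methods recover consistent matrices exactly", {
  for (w in list(c(0.5, 0.3, 0.2), c(0.4, 0.25, 0.2, 0.1, 0.05))) {
    m <- consistent_matrix(w)
    for (method in c("eigenvector", "column_normalized_row_mean")) {
      got <- derive_weights(m, method = method)
      expect_equal(as.numeric(got), w, tolerance = 1e-8)
      expect_equal(sum(as.numeric(got)), 1, tolerance = 1e-9)
    }
    expect_equal(consistency(m)$cr, 0, tolerance = 1e-8)
  }
  # 2x2 consistent matrix: weights proportional to any column
  w2 <- derive_weights(pairwise_matrix(rbind(c(1, 3), c(1 / 3, 1))))
  expect_equal(as.numeric(w2), c(0.75, 0.25), tolerance = 1e-9)
  # all-equal preferences: uniform weights under either method
  id4 <- pairwise_matrix(matrix(1, 4, 4))
  expect_equal(as.numeric(derive_weights(id4)), rep(0.25, 4),
               tolerance = 1e-9)
  expect_equal(
    as.numeric(derive_weights(id4, "column_normalized_row_mean")),
    rep(0.25, 4), tolerance = 1e-12)
})

test_that("power-iteration weights agree with a dense eigensolver", {
  mats <- wheat_barley_matrices()
  for (m in mats) {
    ev <- eigen(unclass(m))
    k <- which.max(Re(ev$values))
    ref <- Re(ev$vectors[, k])
    ref <- ref / sum(ref)
    expect_equal(as.numeric(derive_weights(m)), ref, tolerance = 1e-8)
    expect_equal(consistency(m)$lambda_max, Re(ev$values[k]),
                 tolerance = 1e-8)
  }
})

test_that("lambda_max behaves like a principal eigenvalue estimate", {
  id3 <- pairwise_matrix(matrix(1, 3, 3))
  expect_equal(ahp_lambda_max(id3, rep(1 / 3, 3)), 3.0)
  m2 <- pairwise_matrix(rbind(c(1, 3), c(1 / 3, 1)))
  expect_equal(ahp_lambda_max(m2, derive_weights(m2)), 2.0,
               tolerance = 1e-9)
  # lambda_max >= n for reciprocal matrices, any positive weights
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    v <- matrix(1, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v[i, j] <- sample(c(1 / (9:2), 1, 2:9), 1)
      v[j, i] <- 1 / v[i, j]
    }
    m <- pairwise_matrix(v)
    expect_gte(ahp_lambda_max(m, derive_weights(m)), n - 1e-6)
  }
  expect_error(ahp_lambda_max(id3, c(0, 1, 1)), "positive")
})

test_that("random index lookups match the reference table", {
  expect_identical(random_index(8), 1.41)
  expect_identical(random_index(10), 1.49)
  expect_identical(random_index(2), 0.00)
  expect_identical(random_index(3), 0.58)
  expect_error(random_index(16), "1..15")
  expect_error(random_index(0), "1..15")
})

test_that("consistency flags incoherent preference cycles", {
  cyc <- pairwise_matrix(rbind(c(1, 9, 1 / 9),
                               c(1 / 9, 1, 9),
                               c(9, 1 / 9, 1)))
  rep <- consistency(cyc)
  expect_gt(rep$cr, 0.10)
  expect_false(rep$acceptable)
  # all-equal preferences are perfectly consistent
  rep0 <- consistency(pairwise_matrix(matrix(1, 5, 5)))
  expect_equal(rep0$ci, 0, tolerance = 1e-9)
  expect_equal(rep0$cr, 0, tolerance = 1e-9)
  expect_true(rep0$acceptable)
  # n = 2 reciprocal matrices are always consistent, CR defined as 0
  rep2 <- consistency(pairwise_matrix(rbind(c(1, 7), c(1 / 7, 1))))
  expect_identical(rep2$cr, 0)
  expect_true(rep2$acceptable)
})

test_that("global weights flatten a hierarchy and sum to one", {
  main <- derive_weights(consistent_matrix(c(0.5, 0.3, 0.2)))
  names(main) <- c("A", "B", "C")
  groups <- list(
    A = structure(c(a1 = 0.6, a2 = 0.4), class = "weight_vector"),
    B = structure(c(b1 = 1), class = "weight_vector"),
    C = structure(c(c1 = 0.7, c2 = 0.2, c3 = 0.1),
                  class = "weight_vector"))
  gw <- global_weights(main, groups)
  expect_equal(sum(as.numeric(gw)), 1, tolerance = 1e-12)
  expect_equal(gw[["a1"]], 0.5 * 0.6, tolerance = 1e-9)
  expect_equal(gw[["c3"]], 0.2 * 0.1, tolerance = 1e-9)
  # single group with weight 1 reproduces the group weights
  one <- structure(c(G = 1), class = "weight_vector")
  gw1 <- global_weights(one, list(G = groups$C))
  expect_equal(as.numeric(gw1), as.numeric(groups$C), tolerance = 1e-12)
  # missing group and label collisions are errors
  expect_error(global_weights(main, groups[c("A", "B")]), "no sub-criteria")
  groups_bad <- groups
  names(groups_bad$B) <- "a1"
  expect_error(global_weights(main, groups_bad), "collision")
})

test_that("permissive-mode eigenvector weights respond monotonically to a
           strengthened criterion", {
  base <- rbind(c(1, 2, 2), c(1 / 2, 1, 2), c(1 / 2, 1 / 2, 1))
  w0 <- derive_weights(pairwise_matrix(base))[[1]]
  for (k in c(1.5, 2, 3)) {
    boosted <- base
    boosted[1, -1] <- base[1, -1] * k
    boosted[-1, 1] <- base[-1, 1] / k
    wk <- derive_weights(pairwise_matrix(boosted))[[1]]
    expect_gt(wk, w0)
    w0 <- wk
  }
})

test_that("pairwise CSV round-trips, including fraction cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("criterion,pH,EC,OM",
               "pH,1,3,1/2",
               "EC,1/3,1,1/3",
               "OM,2,3,1"), path)
  m <- read_pairwise_csv(path, level = "chemical")
  expect_equal(unname(unclass(m)[1, 3]), 0.5)
  expect_equal(unname(unclass(m)[2, 1]), 1 / 3, tolerance = 1e-12)
  out <- withr::local_tempfile(fileext = ".csv")
  write_pairwise_csv(m, out)
  m2 <- read_pairwise_csv(out, level = "chemical")
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-9)
  expect_error(parse_ratio("one third"), "unparseable")
})

test_that("consistency reports export as a flat CSV", {
  mats <- wheat_barley_matrices()
  reports <- lapply(mats, consistency)
  path <- withr::local_tempfile(fileext = ".csv")
  write_consistency_csv(reports, path)
  df <- read.csv(path, check.names = FALSE)
  expect_identical(df$statistic, c("lambda_max", "CI", "RI", "CR"))
  expect_equal(df$physical[4], reports$physical$cr, tolerance = 1e-6)
  expect_equal(df$main[1], reports$main$lambda_max, tolerance = 1e-6)
})
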