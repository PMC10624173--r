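# Weighted linear soil quality index SQI = sum_i W_i * X_i on scores
# X_i in [0.1, 1], bridged to a 0-100 index (index100 = 100 * SQI) for
# FAO-style suitability classification: S1 [80,100], S2 [60,80),
# S3 [50,60), N1 [20,50), N2 [0,20). The half-open-upward convention makes
# the classes exhaustive and non-overlapping.

.SQI_CLASSES <- c("S1", "S2", "S3", "N1", "N2")
.SQI_BREAKS <- c(80, 60, 50, 20, 0)

#' Compute the soil quality index per point
#'
#' `SQI = sum(w_i * x_i)` over the weighted parameters. If a point is
#' missing any weighted score, its SQI is `NA` unless
#' `renormalize = TRUE`, in which case the weights of the available
#' parameters are rescaled to sum to 1 for that point (recorded in the
#' result's `renormalized` attribute).
#'
#' @param scores a `score_table` from [score_samples()] (or data.frame
#'   with `id` plus score columns).
#' @param weights a `weight_vector` whose labels are score columns.
#' @param renormalize rescale weights over available scores instead of
#'   propagating `NA` (default `FALSE`).
#' @return a `suitability_result`: data.frame with `id`, `sqi`,
#'   `index100`, `class`; attributes `weights_used`, `catalog_used`,
#'   `renormalized`.
#' @export
compute_sqi <- function(scores, weights, renormalize = FALSE) {
  w <- as.numeric(weights)
  labs <- names(weights)
  if (is.null(labs)) stop("weights must be named", call. = FALSE)
  overlap <- intersect(labs, names(scores))
  if (!length(overlap))
    stop("no overlap between weight labels and score columns",
         call. = FALSE)
  if (length(overlap) < length(labs)) {
    if (!renormalize)
      stop("score columns missing for weighted parameters: ",
           paste(setdiff(labs, overlap), collapse = ", "),
           " (set renormalize = TRUE to rescale)", call. = FALSE)
    w <- w[match(overlap, labs)]
    labs <- overlap
  }
  if (abs(sum(w) - 1) > 1e-6 && !renormalize)
    stop("weights must sum to 1", call. = FALSE)
  X <- as.matrix(scores[, labs, drop = FALSE])
  if (renormalize) {
    avail <- !is.na(X)
    denom <- as.numeric(avail %*% w)
    X0 <- X
    X0[!avail] <- 0
    sqi <- ifelse(denom > 0, as.numeric(X0 %*% w) / denom, NA_real_)
    renorm <- any(denom < sum(w) - 1e-12)
  } else {
    sqi <- as.numeric(X %*% (w / sum(w)))
    renorm <- FALSE
  }
  idx <- 100 * sqi
  cls <- rep(NA_character_, length(idx))
  ok <- !is.na(idx)
  cls[ok] <- classify_sqi(idx[ok])
  out <- data.frame(id = scores$id, sqi = sqi, index100 = idx,
                    class = cls, stringsAsFactors = FALSE)
  structure(out, class = c("suitability_result", "data.frame"),
            weights_used = weights,
            catalog_used = attr(scores, "catalog", exact = TRUE),
            renormalized = renorm)
}

#' Classify a 0-100 suitability index
#'
#' `S1` on `[80, 100]`, `S2` on `[60, 80)`, `S3` on `[50, 60)`, `N1` on
#' `[20, 50)`, `N2` on `[0, 20)`.
#'
#' @param index100 numeric vector in `[0, 100]`.
#' @return character vector of class tags.
#' @export
classify_sqi <- function(index100) {
  if (any(!is.finite(index100)))
    stop("index values must be finite (handle NA upstream)", call. = FALSE)
  if (any(index100 < 0 | index100 > 100))
    stop("index values outside [0, 100]: ",
         paste(utils::head(index100[index100 < 0 | index100 > 100], 3),
               collapse = ", "), call. = FALSE)
  out <- character(length(index100))
  out[index100 >= 80] <- "S1"
  out[index100 >= 60 & index100 < 80] <- "S2"
  out[index100 >= 50 & index100 < 60] <- "S3"
  out[index100 >= 20 & index100 < 50] <- "N1"
  out[index100 < 20] <- "N2"
  out
}

#' Score an interpolated parameter raster
#'
#' Applies the direction-appropriate SSF cell-wise; `NA` cells stay `NA`.
#'
#' @param grid a `raster_grid` of parameter values.
#' @param direction `"more_is_better"` or `"less_is_better"`.
#' @param lower,upper SSF thresholds.
#' @return a `raster_grid` of scores in `[0.1, 1]`.
#' @export
score_raster <- function(grid, direction, lower, upper) {
  f <- if (direction == "more_is_better") ssf_more_is_better
       else if (direction == "less_is_better") ssf_less_is_better
       else stop("unknown direction '", direction, "'", call. = FALSE)
  v <- grid$values
  ok <- !is.na(v)
  v[ok] <- f(v[ok], lower, upper)
  grid$values <- v
  grid
}

#' Combine score rasters into an SQI raster
#'
#' Weighted cell-wise sum of per-parameter score rasters sharing one
#' geometry. Cells missing any weighted score become `NA` unless
#' `renormalize = TRUE`.
#'
#' @param score_rasters named list of `raster_grid`s (names are weight
#'   labels).
#' @param weights a `weight_vector`.
#' @param renormalize rescale weights over available layers per cell.
#' @return a `raster_grid` of SQI values in `[0.1, 1]`.
#' @export
compute_sqi_raster <- function(score_rasters, weights, renormalize = FALSE) {
  labs <- intersect(names(weights), names(score_rasters))
  if (!length(labs))
    stop("no overlap between weight labels and raster names", call. = FALSE)
  w <- as.numeric(weights)[match(labs, names(weights))]
  ref <- score_rasters[[labs[1]]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  denom <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (k in seq_along(labs)) {
    v <- score_rasters[[labs[k]]]$values
    if (!all(dim(v) == dim(acc)))
      stop("score rasters do not share geometry", call. = FALSE)
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + w[k] * v[ok]
    denom[ok] <- denom[ok] + w[k]
    if (!renormalize) acc[!ok] <- NA
  }
  vals <- if (renormalize) ifelse(denom > 0, acc / denom, NA_real_)
          else acc / sum(w)
  ref$values <- vals
  ref
}

#' Classify an SQI raster and overlay mask polygons
#'
#' Cells whose centre falls inside any mask polygon receive that mask's
#' integer category code (10, 11, ... in order of first appearance);
#' remaining cells receive the suitability class code (1 = S1 ... 5 = N2).
#' Masks must be in the raster's (planar) coordinate frame; no
#' reprojection is attempted.
#'
#' @param sqi_raster `raster_grid` of SQI values in `[0.1, 1]`.
#' @param masks optional mask set from [read_geojson_masks()] (a list of
#'   `list(category =, rings = list(data.frame(x, y)))`), or `NULL`.
#' @return a `raster_grid` of integer class codes with attribute
#'   `code_table` (data.frame `code`, `label`).
#' @export
mask_and_map <- function(sqi_raster, masks = NULL) {
  cc <- raster_cell_centers(sqi_raster)
  sqi <- as.vector(t(sqi_raster$values))
  code <- rep(NA_integer_, length(sqi))
  ok <- !is.na(sqi)
  cls <- rep(NA_character_, length(sqi))
  cls[ok] <- classify_sqi(100 * sqi[ok])
  code[ok] <- match(cls[ok], .SQI_CLASSES)
  code_table <- data.frame(code = seq_along(.SQI_CLASSES),
                           label = .SQI_CLASSES,
                           stringsAsFactors = FALSE)
  if (!is.null(masks) && length(masks)) {
    cats <- unique(vapply(masks, `[[`, character(1), "category"))
    mask_codes <- stats::setNames(9L + seq_along(cats), cats)
    code_table <- rbind(code_table,
                        data.frame(code = unname(mask_codes), label = cats,
                                   stringsAsFactors = FALSE))
    claimed <- rep(FALSE, length(sqi))
    for (mk in masks) {
      inside <- rep(FALSE, length(sqi))
      for (ring in mk$rings)
        inside <- inside | .point_in_poly(cc$x, cc$y, ring$x, ring$y)
      take <- inside & !claimed
      code[take] <- mask_codes[[mk$category]]
      claimed <- claimed | inside
    }
  }
  out <- sqi_raster
  out$values <- matrix(code, nrow(sqi_raster$values),
                       ncol(sqi_raster$values), byrow = TRUE)
  attr(out, "code_table") <- code_table
  out
}

#' Read mask polygons from GeoJSON
#'
#' Supports FeatureCollections of Polygon / MultiPolygon features. The
#' mask category is taken from the feature property named by `category`
#' (default `"category"`), falling back to `"mask"`. Only outer rings are
#' used; coordinates are treated as planar metres.
#'
#' @param path GeoJSON file path.
#' @param category property name carrying the category tag.
#' @return list of `list(category, rings)` mask entries.
#' @export
read_geojson_masks <- function(path, category = "category") {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  lapply(feats, function(f) {
    geom <- f$geometry %||% f
    ring_list <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, `[[`, 1),
      stop("unsupported geometry type '", geom$type, "' in ", path,
           call. = FALSE))
    rings <- lapply(ring_list, function(r) {
      m <- do.call(rbind, lapply(r, function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      data.frame(x = m[, 1], y = m[, 2])
    })
    cat_tag <- f$properties[[category]] %||% "mask"
    list(category = as.character(cat_tag), rings = rings)
  })
}

#' Tabulate class areas of a class-coded raster
#'
#' Area per class = cell count times cell area, in hectares; shares are
#' percentages of all classified (non-no-data) cells, so they sum to 100.
#'
#' @param class_raster integer-coded `raster_grid` from [mask_and_map()].
#' @return an `area_table`: data.frame with `class`, `area_ha`,
#'   `share_pct`; attribute `total_ha`.
#' @export
tabulate_areas <- function(class_raster) {
  code <- as.vector(class_raster$values)
  code <- code[!is.na(code)]
  if (!length(code)) stop("no classified cells to tabulate", call. = FALSE)
  ct <- attr(class_raster, "code_table", exact = TRUE)
  cell_ha <- class_raster$cellsize^2 / 1e4
  counts <- table(code)
  labels <- if (!is.null(ct)) ct$label[match(as.integer(names(counts)),
                                             ct$code)]
            else as.character(names(counts))
  out <- data.frame(class = labels,
                    area_ha = as.numeric(counts) * cell_ha,
                    share_pct = 100 * as.numeric(counts) / length(code),
                    stringsAsFactors = FALSE)
  structure(out, class = c("area_table", "data.frame"),
            total_ha = length(code) * cell_ha)
}
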