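# Survey CSV ingestion (tolerant of decimal-comma locales), result
# writers, and the end-to-end pipeline: score -> weights -> interpolate
# -> SQI -> classify -> tabulate -> (optional) validate.

#' Read a point soil-survey table from CSV
#'
#' Expects a header with `x` and `y` coordinate columns (projected
#' metres) and one column per soil parameter; an `id` column is added if
#' absent. Decimal commas (`"28,62"`) are handled: `decimal_mark =
#' "auto"` detects them, or force with `","`. Unparseable numeric cells
#' are reported with row and column.
#'
#' @param path CSV file path.
#' @param decimal_mark `"auto"`, `"."` or `","`.
#' @return a `sample_table` data.frame (`id`, `x`, `y`, parameters).
#'   Columns that fail numeric parsing entirely are kept as character
#'   and flagged with a warning.
#' @export
read_samples <- function(path, decimal_mark = "auto") {
  decimal_mark <- match.arg(decimal_mark, c("auto", ".", ","))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character",
                         sep = if (decimal_mark == ",") ";" else ",")
  if (decimal_mark == "," && ncol(raw) == 1)  # comma-separated after all
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  names(raw)[tolower(names(raw)) == "x"] <- "x"
  names(raw)[tolower(names(raw)) == "y"] <- "y"
  names(raw)[tolower(names(raw)) == "id"] <- "id"
  if (!all(c("x", "y") %in% names(raw)))
    stop("sample CSV must have x and y coordinate columns: ", path,
         call. = FALSE)
  if (decimal_mark == "auto") {
    cells <- unlist(raw[setdiff(names(raw), "id")], use.names = FALSE)
    decimal_mark <- if (any(grepl("^-?[0-9]+,[0-9]+$", cells))) "," else "."
  }
  out <- raw
  for (col in setdiff(names(raw), "id")) {
    v <- raw[[col]]
    if (decimal_mark == ",") v <- gsub(",", ".", v, fixed = TRUE)
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
    if (length(bad)) {
      if (col %in% c("x", "y"))
        stop(sprintf("unparseable coordinate '%s' at row %d, column %s",
                     v[bad[1]], bad[1], col), call. = FALSE)
      warning(sprintf(
        "column '%s' kept as text (unparseable cell '%s' at row %d)",
        col, v[bad[1]], bad[1]), call. = FALSE)
    } else {
      out[[col]] <- num
    }
  }
  if (!"id" %in% names(out)) out$id <- seq_len(nrow(out))
  known <- c("id", "x", "y", names(.ssf_directions()))
  unknown <- setdiff(names(out), known)
  if (length(unknown))
    message("read_samples: non-standard columns preserved: ",
            paste(unknown, collapse = ", "))
  out <- out[, c("id", "x", "y", setdiff(names(out), c("id", "x", "y")))]
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Write a sample table to CSV
#'
#' @param samples a `sample_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline run configuration
#'
#' Any unset input falls back to the built-in defaults: a synthetic
#' survey generated from `seed`, the built-in threshold catalog and the
#' built-in wheat-barley pairwise matrices.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed for all randomness.
#' @param samples_csv optional survey CSV (default: synthesise).
#' @param catalog optional threshold-catalog YAML path.
#' @param matrices optional named list of pairwise-matrix CSV paths with
#'   elements `main`, `physical`, `chemical`, `productivity`.
#' @param masks optional GeoJSON mask path.
#' @param yields optional yield CSV path.
#' @param candidates character vector naming interpolation candidates
#'   (subset of `names(candidate_interpolators())`), or `NULL` for all.
#' @param parameters parameters to interpolate and weight (default: all
#'   weighted parameters present).
#' @param cellsize output raster cell size (m), default 80.
#' @param spacing,corr_length synthetic-survey controls.
#' @param sqi_order `"interpolate_then_score"` (default) or
#'   `"score_then_interpolate"`.
#' @param weight_method see [derive_weights()].
#' @param renormalize see [compute_sqi()].
#' @return a validated `run_config` list.
#' @export
run_config <- function(outdir, seed = 1, samples_csv = NULL, catalog = NULL,
                       matrices = NULL, masks = NULL, yields = NULL,
                       candidates = NULL, parameters = NULL, cellsize = 80,
                       spacing = 400, corr_length = 800,
                       sqi_order = c("interpolate_then_score",
                                     "score_then_interpolate"),
                       weight_method = "eigenvector", renormalize = FALSE) {
  sqi_order <- match.arg(sqi_order)
  for (p in c(samples_csv, catalog, masks, yields, unlist(matrices)))
    if (!is.null(p) && !file.exists(p))
      stop("configured input does not exist: ", p, call. = FALSE)
  if (!is.null(candidates)) {
    bad <- setdiff(candidates, names(candidate_interpolators()))
    if (length(bad))
      stop("unknown interpolation candidate(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 samples_csv = samples_csv, catalog = catalog,
                 matrices = matrices, masks = masks, yields = yields,
                 candidates = candidates, parameters = parameters,
                 cellsize = cellsize, spacing = spacing,
                 corr_length = corr_length, sqi_order = sqi_order,
                 weight_method = weight_method,
                 renormalize = renormalize),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full land-suitability pipeline
#'
#' Executes score -> weights -> interpolation model selection -> SQI ->
#' classification -> area tabulation, and optional yield validation, and
#' writes all reports (weights, consistency, interpolation leaderboard,
#' area table), rasters (SQI and class codes, ESRI ASCII), the class-code
#' sidecar and a JSON run manifest into the output directory.
#'
#' @param config a `run_config`.
#' @return (invisibly) list with `samples`, `weights`, `consistency`,
#'   `leaderboard`, `sqi_raster`, `class_raster`, `areas`, `validation`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  decisions <- character(0)

  samples <- .stage("samples", {
    if (is.null(config$samples_csv)) {
      message("[samples] generating synthetic survey (seed ",
              config$seed, ")")
      spec <- field_spec(seed = config$seed,
                         corr_length = config$corr_length)
      sv <- synthetic_survey(seed = config$seed, spec = spec,
                             spacing = config$spacing)
      write_samples(sv$samples, file.path(config$outdir, "samples.csv"))
      sv$samples
    } else {
      message("[samples] reading ", config$samples_csv)
      read_samples(config$samples_csv)
    }
  })

  catalog <- .stage("catalog", {
    if (is.null(config$catalog)) {
      decisions <- c(decisions,
        "thresholds: built-in class-edge catalog, percentile fallback")
      default_threshold_catalog(samples)
    } else load_threshold_catalog(config$catalog)
  })

  wts <- .stage("weights", {
    message("[weights] AHP weighting (", config$weight_method, ")")
    decisions <- c(decisions, paste0("weight method: ",
                                     config$weight_method))
    if (is.null(config$matrices)) {
      wheat_barley_weights(method = config$weight_method)
    } else {
      mats <- lapply(config$matrices, read_pairwise_csv)
      main_w <- derive_weights(mats$main, method = config$weight_method)
      groups <- lapply(mats[setdiff(names(mats), "main")],
                       derive_weights, method = config$weight_method)
      reports <- lapply(mats, consistency)
      if (!all(vapply(reports, `[[`, logical(1), "acceptable")))
        stop("pairwise matrix with CR > 0.10: ",
             paste(names(reports)[!vapply(reports, `[[`, logical(1),
                                          "acceptable")], collapse = ", "))
      list(global = global_weights(main_w, groups), main = main_w,
           groups = groups, consistency = reports)
    }
  })
  gw <- wts$global
  write_consistency_csv(wts$consistency,
                        file.path(config$outdir, "consistency.csv"))
  wdf <- data.frame(parameter = names(gw), weight = as.numeric(gw))
  utils::write.csv(wdf, file.path(config$outdir, "weights.csv"),
                   row.names = FALSE)

  params <- config$parameters %||%
    intersect(names(gw), names(samples))
  if (!length(params)) stop("stage 'weights' failed: no weighted ",
                            "parameter present in samples", call. = FALSE)
  cand <- if (is.null(config$candidates)) candidate_interpolators()
          else candidate_interpolators()[config$candidates]

  extent <- c(min(samples$x), max(samples$x),
              min(samples$y), max(samples$y)) +
    c(-1, 1, -1, 1) * config$spacing / 2

  sel <- .stage("interpolation", {
    message("[interpolation] LOOCV over ", length(cand),
            " candidate(s) x ", length(params), " parameter(s)")
    lapply(stats::setNames(params, params), function(p)
      select_best(samples, p, cand))
  })
  leaderboard <- do.call(rbind, lapply(params, function(p) {
    lb <- sel[[p]]$leaderboard
    lb$parameter <- p
    lb
  }))
  utils::write.csv(leaderboard,
                   file.path(config$outdir, "leaderboard.csv"),
                   row.names = FALSE)

  sqi_raster <- .stage("sqi", {
    message("[sqi] order: ", config$sqi_order)
    decisions <- c(decisions, paste0("sqi order: ", config$sqi_order))
    cat_use <- catalog[catalog$name %in% params &
                       is.finite(catalog$lower), , drop = FALSE]
    w_use <- gw[names(gw) %in% cat_use$name]
    if (config$sqi_order == "interpolate_then_score") {
      score_rs <- lapply(stats::setNames(cat_use$name, cat_use$name),
        function(p) {
          r <- rasterize_surface(sel[[p]]$best, samples, p, extent,
                                 config$cellsize)
          i <- match(p, cat_use$name)
          score_raster(r, cat_use$direction[i], cat_use$lower[i],
                       cat_use$upper[i])
        })
      compute_sqi_raster(score_rs, w_use, renormalize = TRUE)
    } else {
      scores <- score_samples(samples, cat_use)
      res <- compute_sqi(scores, w_use, renormalize = TRUE)
      pts <- samples[, c("id", "x", "y")]
      pts$sqi <- res$sqi
      best <- select_best(pts, "sqi", cand)
      rasterize_surface(best$best, pts, "sqi", extent, config$cellsize)
    }
  })
  sqi_raster$values <- pmin(pmax(sqi_raster$values, 0.1), 1)
  write_esri_ascii(sqi_raster, file.path(config$outdir, "sqi.asc"))

  class_raster <- .stage("classify", {
    masks <- if (!is.null(config$masks))
      read_geojson_masks(config$masks) else NULL
    mask_and_map(sqi_raster, masks)
  })
  write_esri_ascii(class_raster, file.path(config$outdir, "classes.asc"))
  ct <- attr(class_raster, "code_table")
  writeLines(sprintf("%d\t%s", ct$code, ct$label),
             file.path(config$outdir, "classes_codes.txt"))

  areas <- .stage("tabulate", tabulate_areas(class_raster))
  utils::write.csv(
    data.frame(Suitability = areas$class,
               `Area (ha)` = round(areas$area_ha, 2),
               `Ratio (%)` = round(areas$share_pct, 2),
               check.names = FALSE),
    file.path(config$outdir, "areas.csv"), row.names = FALSE)

  validation <- NULL
  if (!is.null(config$yields)) {
    validation <- .stage("validate", {
      ydf <- read_yields(config$yields, points = samples)
      scores <- score_samples(samples, catalog)
      res <- compute_sqi(scores, gw, renormalize = TRUE)
      merged <- merge(ydf[, c("id", "yield")],
                      data.frame(id = res$id, sqi = res$sqi), by = "id")
      validate_yield(merged)
    })
    utils::write.csv(as.data.frame(validation),
                     file.path(config$outdir, "validation.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    inputs = config[c("samples_csv", "catalog", "masks", "yields")],
    spacing = config$spacing, cellsize = config$cellsize,
    corr_length = config$corr_length, sqi_order = config$sqi_order,
    weight_method = config$weight_method,
    parameters = params,
    candidates = names(cand),
    best_method = vapply(sel, function(s)
      paste(s$best$family, s$best$variant, sep = "_"), character(1)),
    decisions = decisions)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  message("[done] outputs in ", config$outdir)
  invisible(list(samples = samples, weights = wts,
                 consistency = wts$consistency,
                 leaderboard = leaderboard, sqi_raster = sqi_raster,
                 class_raster = class_raster, areas = areas,
                 validation = validation, manifest = manifest))
}
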