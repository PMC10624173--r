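# Minimal regular-grid raster container on planar (projected, metre)
# coordinates. Values are stored north-up: row 1 is the top row, matching
# the ESRI ASCII grid layout used for on-disk exchange.

#' Construct a raster grid
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length (m), square cells.
#' @param nodata value standing for no-data on disk (default -9999);
#'   in-memory no-data is `NA`.
#' @param crs_tag free-text CRS note (e.g. "UTM38N"), not interpreted.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll, yll, cellsize, nodata = -9999,
                        crs_tag = "") {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 1, ncol(values) >= 1, cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs_tag = crs_tag),
            class = "raster_grid")
}

#' Cell-centre coordinates of a raster grid
#'
#' @param grid a `raster_grid`.
#' @return data.frame with `x`, `y`, `row`, `col`, one row per cell in
#'   row-major (north-up) order: row 1 (top) first, left to right, matching
#'   `as.vector(t(grid$values))`.
#' @export
raster_cell_centers <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  cs <- grid$cellsize
  xs <- grid$xll + (seq_len(nc) - 0.5) * cs
  ys <- grid$yll + (nr - seq_len(nr) + 0.5) * cs
  data.frame(x = rep(xs, times = nr),
             y = rep(ys, each = nc),
             row = rep(seq_len(nr), each = nc),
             col = rep(seq_len(nc), times = nr))
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "raster_grid: %d x %d cells of %g m, lower-left (%g, %g)%s\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
    if (nzchar(x$crs_tag)) paste0(" [", x$crs_tag, "]") else ""))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %g, mean %g, max %g; %d NA cells\n",
                min(v), mean(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param grid a `raster_grid`; `NA` cells are written as the grid's
#'   nodata value.
#' @param path output `.asc` path.
#' @param digits significant digits written (default 15, enough for an
#'   exact read-back of doubles in practice).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, digits = 15) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", grid$xll),
    sprintf("yllcorner %.10f", grid$yll),
    sprintf("cellsize %.10f", grid$cellsize),
    sprintf("NODATA_value %g", grid$nodata)), con)
  writeLines(apply(v, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` path.
#' @param crs_tag optional CRS note to attach.
#' @return a `raster_grid` with nodata cells as `NA`.
#' @export
read_esri_ascii <- function(path, crs_tag = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, call. = FALSE)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match header in ", path, call. = FALSE)
  v <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  v[v == nodata] <- NA
  raster_grid(v, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
              nodata = nodata, crs_tag = crs_tag)
}
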