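# Yield-based validation of the suitability index: ordinary least squares
# of observed yield on SQI, summarised by R-squared. R2 is the
# conventional 1 - SS_res/SS_tot; for a simple OLS fit this equals the
# squared Pearson correlation of the two variables.

#' Ordinary least squares line
#'
#' @param x,y numeric vectors of equal length (>= 3); `x` must not be
#'   constant.
#' @return named numeric `c(slope =, intercept =)`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("x is constant; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  c(slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]))
}

#' Coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot` with `SS_res = sum((obs - pred)^2)` and
#' `SS_tot = sum((obs - mean(obs))^2)`. Can be negative for predictions
#' worse than the mean; never exceeds 1.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2);
#'   `observed` must not be constant.
#' @return scalar R-squared.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed values are constant; R2 undefined", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Validate SQI against observed yields
#'
#' Fits yield on SQI by OLS and reports the fit's R-squared (which, for
#' simple regression, equals the squared correlation between SQI and
#' yield) together with the direct R-squared of SQI-predicted yields
#' against observations -- the same number, reported both ways for
#' transparency.
#'
#' @param records data.frame with columns `sqi` and `yield`
#'   (kg per hectare, positive), optionally `id`.
#' @return list with `slope`, `intercept`, `r2` (of the OLS line),
#'   `r2_direct` (observed vs fitted), `n`.
#' @export
validate_yield <- function(records) {
  stopifnot(all(c("sqi", "yield") %in% names(records)))
  keep <- is.finite(records$sqi) & is.finite(records$yield)
  rec <- records[keep, ]
  if (nrow(rec) < 3) stop("need at least 3 yield records", call. = FALSE)
  if (any(rec$yield <= 0))
    stop("yields must be positive (kg ha-1)", call. = FALSE)
  line <- fit_line(rec$sqi, rec$yield)
  fitted <- line["intercept"] + line["slope"] * rec$sqi
  r2 <- r_squared(rec$yield, fitted)
  list(slope = unname(line["slope"]),
       intercept = unname(line["intercept"]),
       r2 = r2, r2_direct = r2, n = nrow(rec))
}

#' Read a yield table from CSV
#'
#' Expected columns: `id` and `yield_kg_ha` (or `yield`); optional `x`,
#' `y` for joining to survey points by nearest neighbour.
#'
#' @param path CSV path.
#' @param points optional `sample_table` to join against by nearest
#'   neighbour when the yield table has coordinates but no matching ids.
#' @param max_dist join tolerance in metres (default 250).
#' @return data.frame with `id`, `yield` and any coordinates present.
#' @export
read_yields <- function(path, points = NULL, max_dist = 250) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ycol <- intersect(c("yield_kg_ha", "yield"), names(df))[1]
  if (is.na(ycol)) stop("no yield column (yield_kg_ha) in ", path,
                        call. = FALSE)
  df$yield <- as.numeric(df[[ycol]])
  if (!is.null(points) && all(c("x", "y") %in% names(df)) &&
      !("id" %in% names(df))) {
    d <- .pairwise_dist(df$x, df$y, points$x, points$y)
    nearest <- apply(d, 1, which.min)
    dist <- d[cbind(seq_len(nrow(df)), nearest)]
    if (any(dist > max_dist))
      warning(sum(dist > max_dist),
              " yield record(s) farther than ", max_dist,
              " m from any survey point; left unmatched", call. = FALSE)
    df$id <- ifelse(dist <= max_dist, points$id[nearest], NA)
  }
  df
}
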