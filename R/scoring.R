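# Standard scoring functions (SSF): piecewise-linear rescaling of a soil
# parameter to a dimensionless suitability score in [0.1, 1]. "More is
# better" ramps up from 0.1 at the lower threshold L to 1 at the upper
# threshold U; "less is better" is its mirror. Both branches meet at 0.55
# at the midpoint and satisfy pos(x) + neg(x) = 1.1 for all x.

#' More-is-better standard scoring function
#'
#' @param x parameter value(s), in parameter units. `NA` propagates.
#' @param L lower threshold: at or below it the score is 0.1.
#' @param U upper threshold: at or above it the score is 1.
#' @return score(s) in `[0.1, 1]`.
#' @export
ssf_more_is_better <- function(x, L, U) {
  stopifnot(is.numeric(L), is.numeric(U), length(L) == 1, length(U) == 1,
            is.finite(L), is.finite(U))
  if (L >= U) stop("SSF thresholds require L < U", call. = FALSE)
  if (any(is.nan(x) | is.infinite(x)))
    stop("non-finite parameter value passed to SSF", call. = FALSE)
  s <- 0.1 + 0.9 * (x - L) / (U - L)
  pmin(pmax(s, 0.1), 1)
}

#' Less-is-better standard scoring function
#'
#' Mirror of [ssf_more_is_better()]: 1 at or below `L`, 0.1 at or above
#' `U`, linear between.
#'
#' @inheritParams ssf_more_is_better
#' @return score(s) in `[0.1, 1]`.
#' @export
ssf_less_is_better <- function(x, L, U) {
  stopifnot(is.numeric(L), is.numeric(U), length(L) == 1, length(U) == 1,
            is.finite(L), is.finite(U))
  if (L >= U) stop("SSF thresholds require L < U", call. = FALSE)
  if (any(is.nan(x) | is.infinite(x)))
    stop("non-finite parameter value passed to SSF", call. = FALSE)
  s <- 1 - 0.9 * (x - L) / (U - L)
  pmin(pmax(s, 0.1), 1)
}

# Scoring direction of each indicator. Positive: a larger value is better
# for wheat-barley (depth, AWC, HC, clay, CEC, OM and the nutrients);
# negative: a larger value is worse (slope, BD, sand, silt, pH on alkaline
# soils, EC, CaCO3, Na, ESP).
.ssf_directions <- function() {
  c(Clay = "more_is_better", Silt = "less_is_better", Sand = "less_is_better",
    HC = "more_is_better", BD = "less_is_better", AWC = "more_is_better",
    Slope = "less_is_better", Depth = "more_is_better",
    pH = "less_is_better", EC = "less_is_better", OM = "more_is_better",
    CaCO3 = "less_is_better", CEC = "more_is_better", ESP = "less_is_better",
    N = "more_is_better", P = "more_is_better", K = "more_is_better",
    Ca = "more_is_better", Mg = "more_is_better", Na = "less_is_better",
    Fe = "more_is_better", Cu = "more_is_better", Zn = "more_is_better",
    Mn = "more_is_better")
}

# Numeric suitability-class edges for wheat farming where the standard
# requirement tables give them: L is the worst-class edge, U the fully
# suitable (S1) edge, oriented so that the direction-appropriate SSF ramps
# between them. Parameters whose requirement rows are categorical,
# one-sided or non-monotone (texture fractions, HC, Cu, Fe) fall back to
# dataset percentiles.
.class_edge_thresholds <- function() {
  list(
    Depth = c(20, 120), Slope = c(0, 30), BD = c(1.3, 1.8),
    AWC = c(15, 50), pH = c(7.0, 8.5), EC = c(4, 12), CaCO3 = c(30, 60),
    OM = c(0.5, 2), CEC = c(8, 16), ESP = c(10, 20),
    N = c(0.045, 0.32), P = c(2.5, 80), K = c(0.13, 2.56),
    Ca = c(1.19, 50), Mg = c(0.42, 12.5), Na = c(0.20, 2.0),
    Mn = c(4, 170), Zn = c(0.25, 1))
}

.ssf_units <- function() {
  c(Clay = "%", Silt = "%", Sand = "%", HC = "cm h-1", BD = "g cm-3",
    AWC = "%", Slope = "%", Depth = "cm", pH = "", EC = "dS m-1", OM = "%",
    CaCO3 = "%", CEC = "cmol kg-1", ESP = "%", N = "%", P = "mg kg-1",
    K = "cmol kg-1", Ca = "cmol kg-1", Mg = "cmol kg-1", Na = "cmol kg-1",
    Fe = "mg kg-1", Cu = "mg kg-1", Zn = "mg kg-1", Mn = "mg kg-1")
}

#' Built-in indicator threshold catalog
#'
#' Returns the scoring catalog for the 24 wheat-barley soil indicators: the
#' SSF direction of each parameter, and lower/upper thresholds `L < U`.
#' Where published wheat suitability-class tables give numeric class edges,
#' `L` is the worst-class edge and `U` the fully-suitable (S1) edge (rule
#' `"class_edges"`). For parameters without a usable numeric requirement
#' row (clay, silt, sand, HC, Cu, Fe) thresholds are the 5th/95th
#' percentiles of the supplied survey (rule `"percentiles"`); these entries
#' have `NA` thresholds when no survey is given.
#'
#' @param samples optional `sample_table` (see [read_samples()]) used to
#'   fill percentile-rule thresholds.
#' @param probs percentile pair for the fallback rule (default
#'   `c(0.05, 0.95)`).
#' @return an `indicator_catalog`: a data.frame with columns `name`,
#'   `direction`, `lower`, `upper`, `units`, `rule`.
#' @export
default_threshold_catalog <- function(samples = NULL, probs = c(0.05, 0.95)) {
  dirs <- .ssf_directions()
  edges <- .class_edge_thresholds()
  units <- .ssf_units()
  nm <- names(dirs)
  lower <- upper <- rep(NA_real_, length(nm))
  rule <- rep("percentiles", length(nm))
  for (i in seq_along(nm)) {
    if (!is.null(edges[[nm[i]]])) {
      lower[i] <- edges[[nm[i]]][1]
      upper[i] <- edges[[nm[i]]][2]
      rule[i] <- "class_edges"
    } else if (!is.null(samples) && nm[i] %in% names(samples)) {
      q <- stats::quantile(samples[[nm[i]]], probs = probs, na.rm = TRUE,
                           names = FALSE)
      if (q[1] < q[2]) {
        lower[i] <- q[1]
        upper[i] <- q[2]
      }
    }
  }
  cat <- data.frame(name = nm, direction = unname(dirs), lower = lower,
                    upper = upper, units = unname(units[nm]), rule = rule,
                    stringsAsFactors = FALSE)
  class(cat) <- c("indicator_catalog", "data.frame")
  cat
}

#' Load an indicator threshold catalog
#'
#' Accepts a YAML file path or an already-parsed list. Each entry is keyed
#' by parameter name and provides `direction`, `lower`, `upper` and
#' optionally `units` and `rule`.
#'
#' @param source YAML path, or a named list of per-parameter entries.
#' @return an `indicator_catalog` data.frame.
#' @export
load_threshold_catalog <- function(source) {
  if (is.character(source) && length(source) == 1) {
    source <- yaml::read_yaml(source)
  }
  if (!is.list(source) || length(source) == 0)
    stop("threshold catalog source is empty or not a mapping", call. = FALSE)
  rows <- lapply(names(source), function(nm) {
    e <- source[[nm]]
    dir <- e$direction
    if (is.null(dir) || !dir %in% c("more_is_better", "less_is_better"))
      stop(sprintf("catalog entry '%s': unknown or missing direction '%s'",
                   nm, if (is.null(dir)) "" else dir), call. = FALSE)
    lo <- as.numeric(e$lower %||% NA)
    up <- as.numeric(e$upper %||% NA)
    if (is.finite(lo) && is.finite(up) && lo >= up)
      stop(sprintf("catalog entry '%s': lower (%g) must be < upper (%g)",
                   nm, lo, up), call. = FALSE)
    data.frame(name = nm, direction = dir, lower = lo, upper = up,
               units = as.character(e$units %||% ""),
               rule = as.character(e$rule %||% "config"),
               stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, rows)
  class(cat) <- c("indicator_catalog", "data.frame")
  cat
}

#' Write an indicator catalog to a YAML config
#'
#' Inverse of [load_threshold_catalog()]; a write/read round trip
#' reproduces the catalog exactly.
#'
#' @param catalog an `indicator_catalog`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_threshold_catalog <- function(catalog, path) {
  entries <- lapply(seq_len(nrow(catalog)), function(i) {
    e <- list(direction = catalog$direction[i],
              lower = catalog$lower[i], upper = catalog$upper[i],
              units = catalog$units[i], rule = catalog$rule[i])
    if (is.na(e$lower)) e$lower <- NULL
    if (is.na(e$upper)) e$upper <- NULL
    e
  })
  names(entries) <- catalog$name
  yaml::write_yaml(entries, path, precision = 15)
  invisible(path)
}

#' Score a sample table against an indicator catalog
#'
#' Applies the direction-appropriate SSF to every catalog parameter found
#' in the sample table. Catalog parameters missing from the table, and
#' catalog entries with unresolved (`NA`) thresholds, are dropped with a
#' warning. Missing measurements propagate as `NA` scores and are flagged
#' in the `n_missing` attribute.
#'
#' @param samples a `sample_table` (data.frame with `id`, `x`, `y` and one
#'   column per parameter).
#' @param catalog an `indicator_catalog`.
#' @return a `score_table`: data.frame with `id` and one score column per
#'   scored parameter; attributes `catalog` (the rows used) and
#'   `n_missing` (named count of NA scores per parameter).
#' @export
score_samples <- function(samples, catalog) {
  usable <- catalog[is.finite(catalog$lower) & is.finite(catalog$upper), ,
                    drop = FALSE]
  dropped <- setdiff(catalog$name, usable$name)
  if (length(dropped))
    warning("catalog entries without numeric thresholds skipped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  present <- usable$name %in% names(samples)
  if (!any(present))
    stop("no overlap between catalog parameters and sample columns",
         call. = FALSE)
  if (any(!present))
    warning("catalog parameters absent from samples: ",
            paste(usable$name[!present], collapse = ", "), call. = FALSE)
  usable <- usable[present, , drop = FALSE]
  out <- data.frame(id = samples$id, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(usable))) {
    p <- usable$name[i]
    f <- if (usable$direction[i] == "more_is_better") ssf_more_is_better
         else ssf_less_is_better
    out[[p]] <- f(samples[[p]], usable$lower[i], usable$upper[i])
  }
  n_missing <- vapply(out[-1], function(col) sum(is.na(col)), integer(1))
  if (any(n_missing > 0))
    warning("missing scores (excluded from SQI downstream): ",
            paste(sprintf("%s=%d", names(n_missing)[n_missing > 0],
                          n_missing[n_missing > 0]), collapse = ", "),
            call. = FALSE)
  structure(out, class = c("score_table", "data.frame"),
            catalog = usable, n_missing = n_missing)
}
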