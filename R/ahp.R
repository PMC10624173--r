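#' Construct a pairwise-comparison matrix
#'
#' Builds the basic AHP object: a square reciprocal matrix of importance
#' ratios on the Saaty scale, one per hierarchy level. The matrix is
#' validated on construction (see [validate_pairwise()]).
#'
#' @param values numeric square matrix of positive importance ratios.
#' @param labels character vector of criterion names, one per row/column.
#'   Defaults to the dimnames of `values`, or `C1..Cn`.
#' @param level tag identifying the hierarchy level the matrix belongs to,
#'   one of `"main"`, `"physical"`, `"chemical"`, `"productivity"`,
#'   `"custom"`.
#' @param strict_saaty logical; if `TRUE`, off-diagonal entries must lie on
#'   the discrete Saaty scale 1/9..1/2, 1, 2..9. Expert matrices entered by
#'   hand should be checked strictly; matrices transcribed from published
#'   tables that contain values such as 0.5 can be loaded with
#'   `strict_saaty = FALSE`.
#' @return an object of class `pairwise_matrix`: the validated matrix with
#'   attributes `labels` and `level`.
#' @examples
#' m <- pairwise_matrix(rbind(c(1, 2, 2), c(1/2, 1, 2), c(1/2, 1/2, 1)),
#'                      labels = c("physical", "chemical", "productivity"),
#'                      level = "main")
#' derive_weights(m)
#' @export
pairwise_matrix <- function(values, labels = NULL, level = "custom",
                            strict_saaty = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("pairwise matrix must be a square numeric matrix", call. = FALSE)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- paste0("C", seq_len(nrow(values)))
  }
  if (length(labels) != nrow(values))
    stop("length(labels) must equal nrow(values)", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  level <- match.arg(level,
                     c("main", "physical", "chemical", "productivity", "custom"))
  x <- structure(values, class = "pairwise_matrix",
                 labels = labels, level = level)
  validate_pairwise(x, strict_saaty = strict_saaty)
}

#' Validate a pairwise-comparison matrix
#'
#' Checks squareness, positivity, a unit diagonal, reciprocity
#' (`a_ij * a_ji = 1` within relative tolerance 1e-6) and, optionally, that
#' every off-diagonal entry lies on the discrete Saaty scale. Violations are
#' reported with the offending indices.
#'
#' @param matrix a `pairwise_matrix` or plain square numeric matrix.
#' @param strict_saaty logical; enforce the discrete 1/9..9 Saaty scale.
#' @return the (unchanged) matrix, invisibly classed as `pairwise_matrix`.
#' @export
validate_pairwise <- function(matrix, strict_saaty = FALSE) {
  v <- unclass(matrix)
  if (!is.matrix(v) || !is.numeric(v) || nrow(v) != ncol(v))
    stop("pairwise matrix must be a square numeric matrix", call. = FALSE)
  n <- nrow(v)
  if (n < 2) stop("pairwise matrix needs at least 2 criteria", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0)) {
    bad <- which(!is.finite(v) | v <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive or non-finite entry at [%d, %d]",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (any(abs(diag(v) - 1) > 1e-9)) {
    i <- which(abs(diag(v) - 1) > 1e-9)[1]
    stop(sprintf("diagonal entry [%d, %d] is %g, expected 1", i, i, v[i, i]),
         call. = FALSE)
  }
  rec <- v * t(v)
  if (any(abs(rec - 1) > 1e-6)) {
    bad <- which(abs(rec - 1) > 1e-6, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "reciprocity violated at [%d, %d]: %g * %g != 1",
      bad[1], bad[2], v[bad[1], bad[2]], v[bad[2], bad[1]]), call. = FALSE)
  }
  if (strict_saaty) {
    scale <- c(1 / (9:2), 1, 2:9)
    off <- v[row(v) != col(v)]
    onscale <- vapply(off, function(x) any(abs(x - scale) < 1e-9), logical(1))
    if (any(!onscale)) {
      idx <- which(row(v) != col(v), arr.ind = TRUE)[which(!onscale)[1], ]
      stop(sprintf("entry [%d, %d] = %g is not on the Saaty 1/9..9 scale",
                   idx[1], idx[2], v[idx[1], idx[2]]), call. = FALSE)
    }
  }
  if (!inherits(matrix, "pairwise_matrix")) {
    labels <- rownames(v)
    if (is.null(labels)) labels <- paste0("C", seq_len(n))
    matrix <- structure(v, class = "pairwise_matrix",
                        labels = labels, level = "custom")
  }
  invisible(matrix)
}

#' Derive criterion weights from a pairwise matrix
#'
#' The default method is the principal right eigenvector, computed by power
#' iteration from a uniform start vector (deterministic; convergence when
#' the relative change drops below 1e-10, at most 10,000 iterations). The
#' alternative `"column_normalized_row_mean"` divides each column by its sum
#' and averages the rows -- the approximation commonly described in applied
#' AHP texts. For a perfectly consistent matrix both methods coincide.
#'
#' @param matrix a `pairwise_matrix` (or matrix accepted by
#'   [validate_pairwise()]).
#' @param method `"eigenvector"` (default) or
#'   `"column_normalized_row_mean"`.
#' @return an object of class `weight_vector`: a named numeric vector
#'   summing to 1, with attribute `method`.
#' @export
derive_weights <- function(matrix,
                           method = c("eigenvector",
                                      "column_normalized_row_mean")) {
  method <- match.arg(method)
  matrix <- validate_pairwise(matrix)
  v <- unclass(matrix)
  n <- nrow(v)
  labels <- attr(matrix, "labels")
  if (method == "eigenvector") {
    w <- rep(1 / n, n)
    converged <- FALSE
    for (it in seq_len(10000L)) {
      w1 <- as.numeric(v %*% w)
      w1 <- w1 / sum(w1)
      if (max(abs(w1 - w) / pmax(w, .Machine$double.eps)) < 1e-10) {
        w <- w1
        converged <- TRUE
        break
      }
      w <- w1
    }
    if (!converged)
      stop("power iteration did not converge; matrix is degenerate",
           call. = FALSE)
  } else {
    w <- rowMeans(sweep(v, 2, colSums(v), "/"))
    w <- w / sum(w)
  }
  weight_vector(w, labels, method)
}

#' @keywords internal
weight_vector <- function(weights, labels, method = "eigenvector") {
  weights <- as.numeric(weights)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) weights <- weights / s
  names(weights) <- labels
  structure(weights, class = "weight_vector", method = method)
}

#' Principal eigenvalue estimate of a pairwise matrix
#'
#' Computes `lambda_max` as the mean over criteria of the component-wise
#' ratios `(A w)_i / w_i`. When `w` is the principal eigenvector all ratios
#' are equal and this is the principal eigenvalue exactly; for approximate
#' weight vectors it is the usual AHP estimate. Always `>= n` (up to 1e-6)
#' for valid reciprocal matrices.
#'
#' @param matrix a `pairwise_matrix`.
#' @param weights a `weight_vector` (or positive numeric vector) aligned
#'   with the matrix.
#' @return scalar `lambda_max`.
#' @export
ahp_lambda_max <- function(matrix, weights) {
  v <- unclass(validate_pairwise(matrix))
  w <- as.numeric(weights)
  if (length(w) != nrow(v))
    stop("weights length does not match matrix order", call. = FALSE)
  if (any(w <= 0)) stop("weights must be strictly positive", call. = FALSE)
  mean(as.numeric(v %*% w) / w)
}

#' Random consistency index
#'
#' Tabulated mean consistency index of random reciprocal matrices, used as
#' the denominator of the consistency ratio. Defined for matrix orders
#' 1 through 15.
#'
#' @param n matrix order (1..15).
#' @return the random index RI(n).
#' @export
random_index <- function(n) {
  ri <- c(0.00, 0.00, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41,
          1.45, 1.49, 1.51, 1.48, 1.56, 1.57, 1.59)
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 1 || n > 15)
    stop("random index is tabulated for integer orders 1..15", call. = FALSE)
  ri[n]
}

#' Consistency report for a pairwise matrix
#'
#' Computes `lambda_max`, the consistency index
#' `CI = (lambda_max - n) / (n - 1)`, the tabulated random index RI and the
#' consistency ratio `CR = CI / RI`. A matrix is acceptable when
#' `CR <= 0.10`. Orders 1 and 2 are always consistent; their CR is defined
#' as 0 (RI is 0 there, so the ratio is otherwise undefined).
#'
#' @param matrix a `pairwise_matrix`.
#' @param weights optional `weight_vector`; defaults to the principal
#'   eigenvector of `matrix`.
#' @return an object of class `consistency_report`: a list with elements
#'   `lambda_max`, `n`, `ci`, `ri`, `cr`, `acceptable`.
#' @export
consistency <- function(matrix, weights = NULL) {
  matrix <- validate_pairwise(matrix)
  n <- nrow(matrix)
  if (is.null(weights)) weights <- derive_weights(matrix)
  lm <- ahp_lambda_max(matrix, weights)
  if (n <= 2) {
    ci <- 0
    cr <- 0
    ri <- 0
  } else {
    ci <- (lm - n) / (n - 1)
    ri <- random_index(n)
    cr <- ci / ri
  }
  structure(list(lambda_max = lm, n = n, ci = ci, ri = ri, cr = cr,
                 acceptable = cr <= 0.10),
            class = "consistency_report")
}

#' Flatten a two-level AHP hierarchy into global weights
#'
#' Multiplies each sub-criterion's within-group weight by the weight of its
#' group in the main-criteria vector. Because both levels sum to 1, the
#' flattened vector sums to 1.
#'
#' @param main `weight_vector` over the main criteria (group labels).
#' @param groups named list mapping each main label to that group's
#'   `weight_vector` over its sub-criteria.
#' @return a `weight_vector` over all sub-criteria, in group order.
#' @export
global_weights <- function(main, groups) {
  main_w <- as.numeric(main)
  main_l <- names(main)
  if (is.null(main_l)) stop("main weights must be named", call. = FALSE)
  missing <- setdiff(main_l, names(groups))
  if (length(missing))
    stop("no sub-criteria group for main label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- numeric(0)
  for (g in main_l) {
    gw <- groups[[g]]
    s <- sum(as.numeric(gw))
    if (abs(s - 1) > 1e-6)
      stop(sprintf("group '%s' weights sum to %g, expected 1", g, s),
           call. = FALSE)
    part <- main_w[match(g, main_l)] * as.numeric(gw)
    names(part) <- names(gw)
    out <- c(out, part)
  }
  if (anyDuplicated(names(out)))
    stop("sub-criterion label collision across groups: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
         call. = FALSE)
  weight_vector(out, names(out), method = attr(main, "method") %||% "eigenvector")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("Pairwise comparison matrix (%s level, n = %d)\n",
              attr(x, "level"), nrow(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("AHP weights (%s), sum = %g\n", attr(x, "method"),
              sum(as.numeric(x))))
  print(round(stats::setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "lambda_max = %.6f  n = %d\nCI = %.6f  RI = %.2f  CR = %.6f  [%s]\n",
    x$lambda_max, x$n, x$ci, x$ri, x$cr,
    if (x$acceptable) "consistent (CR <= 0.10)" else "NOT consistent"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
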