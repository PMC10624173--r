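# CSV ingestion for expert pairwise matrices and export of consistency
# reports. Cells may be decimals or fraction strings ("1/3"), the form in
# which judgment tables are usually typed up.

#' Parse importance ratios written as decimals or fractions
#'
#' @param x character or numeric vector; fraction strings like `"1/3"` are
#'   evaluated as ratios.
#' @return numeric vector.
#' @export
parse_ratio <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  frac <- grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", x)
  if (any(frac)) {
    parts <- strsplit(x[frac], "/")
    out[frac] <- vapply(parts, function(p)
      as.numeric(p[1]) / as.numeric(p[2]), numeric(1))
  }
  bad <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(bad))
    stop("unparseable ratio cell(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  out
}

#' Read a pairwise-comparison matrix from CSV
#'
#' Layout: a header row and a first column both carrying the criterion
#' labels; remaining cells are ratios, as decimals or fractions (`"1/3"`).
#'
#' @param path CSV file path.
#' @param level hierarchy-level tag, see [pairwise_matrix()].
#' @param strict_saaty enforce the discrete Saaty scale (default `FALSE`,
#'   since transcribed tables often carry 0.5 and similar).
#' @return a `pairwise_matrix`.
#' @export
read_pairwise_csv <- function(path, level = "custom", strict_saaty = FALSE) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(raw[[1]])
  cells <- raw[, -1, drop = FALSE]
  if (nrow(cells) != ncol(cells))
    stop("pairwise CSV is not square: ", nrow(cells), " rows vs ",
         ncol(cells), " ratio columns", call. = FALSE)
  v <- matrix(parse_ratio(as.character(unlist(cells))),
              nrow = nrow(cells), ncol = ncol(cells))
  dimnames(v) <- list(labels, labels)
  pairwise_matrix(v, labels = labels, level = level,
                  strict_saaty = strict_saaty)
}

#' Write a pairwise-comparison matrix to CSV
#'
#' @param matrix a `pairwise_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pairwise_csv <- function(matrix, path) {
  v <- unclass(matrix)
  df <- data.frame(criterion = rownames(v), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export consistency reports as a flat CSV
#'
#' One column per hierarchy, rows `lambda_max`, `CI`, `RI`, `CR` -- the
#' layout in which AHP consistency summaries are conventionally tabulated.
#'
#' @param reports named list of `consistency_report` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_consistency_csv <- function(reports, path) {
  stopifnot(length(reports) > 0)
  m <- vapply(reports, function(r)
    c(lambda_max = r$lambda_max, CI = r$ci, RI = r$ri, CR = r$cr),
    numeric(4))
  df <- data.frame(statistic = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
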