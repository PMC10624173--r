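# Built-in expert judgment matrices for the wheat-barley land-evaluation
# hierarchy used on semi-arid Eastern Anatolian survey soils: 24 indicators
# grouped into physical, chemical and productivity criteria, plus the 3x3
# main-criteria comparison. Entries are verbatim expert ratios and include
# off-Saaty decimals, so strict scale checking is off when constructing.

#' Pairwise matrices of the wheat-barley suitability hierarchy
#'
#' Returns the four expert pairwise-comparison matrices that define the
#' default weighting hierarchy for wheat-barley land evaluation: the 8x8
#' physical block (clay, silt, sand, hydraulic conductivity, bulk density,
#' available water capacity, slope, depth), the 6x6 chemical block (pH, EC,
#' organic matter, CaCO3, CEC, ESP), the 10x10 productivity block
#' (N, P, K, Ca, Mg, Na, Fe, Cu, Zn, Mn) and the 3x3 main-criteria
#' comparison.
#'
#' @return named list of `pairwise_matrix` objects with elements
#'   `main`, `physical`, `chemical`, `productivity`.
#' @examples
#' m <- wheat_barley_matrices()
#' derive_weights(m$main)
#' consistency(m$physical)
#' @export
wheat_barley_matrices <- function() {
  phys_labels <- c("Clay", "Silt", "Sand", "HC", "BD", "AWC", "Slope", "Depth")
  phys <- matrix(c(
    1,     3, 3, 2,   2,   1/2, 1/3, 1/2,
    1/3,   1, 1/3, 1/5, 1/5, 1/5, 1/3, 1/3,
    1/3,   3, 1, 1/3, 1/3, 1/3, 1/3, 1/3,
    1/2,   5, 3, 1,   1/3, 1/5, 1/2, 1/3,
    1/2,   5, 3, 3,   1,   1/3, 1/3, 1/2,
    2,     5, 3, 5,   3,   1,   1/2, 1/2,
    3,     3, 3, 2,   3,   2,   1,   3,
    2,     3, 3, 3,   2,   2,   1/3, 1
  ), nrow = 8, byrow = TRUE, dimnames = list(phys_labels, phys_labels))

  chem_labels <- c("pH", "EC", "OM", "CaCO3", "CEC", "ESP")
  chem <- matrix(c(
    1,   3, 1/2, 3, 1/3, 3,
    1/3, 1, 1/3, 1/3, 1/3, 1/3,
    2,   3, 1,   3, 2,   3,
    1/3, 3, 1/3, 1, 1/3, 1/3,
    3,   3, 1/2, 3, 1,   3,
    1/3, 3, 1/3, 3, 1/3, 1
  ), nrow = 6, byrow = TRUE, dimnames = list(chem_labels, chem_labels))

  prod_labels <- c("N", "P", "K", "Ca", "Mg", "Na", "Fe", "Cu", "Zn", "Mn")
  prod <- matrix(c(
    1,   2,   3,   3,   5,   7, 5,   5,   3,   5,
    1/2, 1,   3,   5,   7,   7, 3,   3,   3,   5,
    1/3, 1/3, 1,   3,   3,   7, 3,   3,   3,   5,
    1/3, 1/5, 1/3, 1,   2,   3, 1/5, 1/3, 1/5, 1/3,
    1/5, 1/7, 1/3, 1/2, 1,   3, 1/5, 1/3, 1/5, 1/3,
    1/7, 1/7, 1/7, 1/3, 1/3, 1, 1/5, 1/3, 1/3, 1/3,
    1/5, 1/3, 1/3, 5,   5,   5, 1,   3,   3,   3,
    1/5, 1/3, 1/3, 3,   3,   3, 1/3, 1,   1/3, 3,
    1/3, 1/3, 1/3, 5,   5,   3, 1/3, 3,   1,   3,
    1/5, 1/5, 1/5, 3,   3,   3, 1/3, 1/3, 1/3, 1
  ), nrow = 10, byrow = TRUE, dimnames = list(prod_labels, prod_labels))

  main_labels <- c("physical", "chemical", "productivity")
  main <- matrix(c(
    1,   2,   2,
    0.5, 1,   2,
    0.5, 0.5, 1
  ), nrow = 3, byrow = TRUE, dimnames = list(main_labels, main_labels))

  list(
    main = pairwise_matrix(main, level = "main"),
    physical = pairwise_matrix(phys, level = "physical"),
    chemical = pairwise_matrix(chem, level = "chemical"),
    productivity = pairwise_matrix(prod, level = "productivity")
  )
}

#' Global indicator weights of the wheat-barley hierarchy
#'
#' Convenience wrapper: derives weights for all four built-in matrices,
#' certifies their consistency and flattens the hierarchy into one global
#' weight per soil indicator.
#'
#' @param method weight derivation method, see [derive_weights()].
#' @param require_consistent abort if any level has CR > 0.10
#'   (default `TRUE`).
#' @return list with elements `global` (a `weight_vector` over the 24
#'   indicators), `main`, `groups` (per-level weight vectors) and
#'   `consistency` (per-level `consistency_report`s).
#' @export
wheat_barley_weights <- function(method = "eigenvector",
                                 require_consistent = TRUE) {
  mats <- wheat_barley_matrices()
  main_w <- derive_weights(mats$main, method = method)
  groups <- lapply(mats[c("physical", "chemical", "productivity")],
                   derive_weights, method = method)
  reports <- lapply(mats, consistency)
  if (require_consistent && !all(vapply(reports, `[[`, logical(1), "acceptable")))
    stop("pairwise matrix with CR > 0.10: ",
         paste(names(reports)[!vapply(reports, `[[`, logical(1), "acceptable")],
               collapse = ", "), call. = FALSE)
  list(global = global_weights(main_w, groups),
       main = main_w, groups = groups, consistency = reports)
}
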