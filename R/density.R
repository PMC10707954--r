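#' Convert a completed table to nutrient density per 100 kcal
#'
#' Rescales every nutrient from "per 100 g edible portion" to "per
#' 100 kcal": \eqn{v^{dens}_j = 100 \, v_j / \mathrm{energy}}. Density
#' removes the diluting effect of water, so the water and energy columns
#' are dropped from the result. Foods whose energy falls below
#' `min_energy` are removed first: for waters, teas and other
#' near-zero-energy items the division is undefined or explosive.
#'
#' @param completed a fully observed [food_table()] (e.g. the `completed`
#'   element of [fit_impute()]).
#' @param min_energy foods with energy (kcal/100 g) strictly below this
#'   are dropped (default 5).
#' @return a `nutrient_matrix`: list with `foods` (food_id, group_id,
#'   name of retained foods), `nutrients` (codes, excluding energy and
#'   water), `values` (foods x nutrients, per 100 kcal) and `dropped`
#'   (descriptors of removed foods).
#' @export
to_per_100kcal <- function(completed, min_energy = 5) {
  stopifnot(inherits(completed, "food_table"))
  if (anyNA(completed$values))
    stop("table still has missing values; impute first")
  ecode <- energy_code(completed)
  wcode <- water_code(completed)
  energy <- completed$values[, ecode]
  keep <- energy >= min_energy
  if (!any(keep)) stop("all foods dropped by the min_energy rule")
  codes <- setdiff(completed$panel$code, c(ecode, wcode))
  vals <- completed$values[keep, codes, drop = FALSE] * (100 / energy[keep])
  # self-consistency: the energy column itself converts to exactly 100
  stopifnot(all(abs(completed$values[keep, ecode] * 100 / energy[keep] - 100)
                < 1e-9))
  structure(list(foods = completed$foods[keep, , drop = FALSE],
                 nutrients = codes,
                 values = vals,
                 dropped = completed$foods[!keep, , drop = FALSE],
                 min_energy = min_energy),
            class = "nutrient_matrix")
}

#' @export
print.nutrient_matrix <- function(x, ...) {
  cat("nutrient_matrix:", nrow(x$values), "foods x", length(x$nutrients),
      "nutrients (per 100 kcal)\n")
  if (nrow(x$dropped))
    cat("  dropped", nrow(x$dropped), "foods with energy <", x$min_energy,
        "kcal/100 g\n")
  invisible(x)
}

#' @export
dim.nutrient_matrix <- function(x) dim(x$values)

#' Remove nutrients from a density matrix
#'
#' Used for the "without PFC" mapping variant, in which protein, fat and
#' carbohydrate are removed to expose the contribution of the remaining
#' nutrients to the map.
#'
#' @param matrix a `nutrient_matrix` from [to_per_100kcal()].
#' @param codes nutrient codes to drop; must all be present.
#' @return a `nutrient_matrix` restricted to the complementary nutrients.
#' @export
drop_nutrients <- function(matrix, codes) {
  stopifnot(inherits(matrix, "nutrient_matrix"))
  unknown <- setdiff(codes, matrix$nutrients)
  if (length(unknown))
    stop("unknown nutrient code(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(matrix$nutrients, codes)
  out <- matrix
  out$nutrients <- keep
  out$values <- matrix$values[, keep, drop = FALSE]
  out
}

#' Macronutrient codes (protein, fat, carbohydrate)
#'
#' @return character vector of the three PFC codes.
#' @export
pfc_codes <- function() c("PROT", "FAT", "CHOCDF")
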