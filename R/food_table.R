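#' Food-composition table container
#'
#' A `food_table` bundles a nutrient panel (the column metadata), the food
#' descriptors, and a numeric value matrix in which `NA` marks a missing
#' (unreported) measurement. All values are per 100 g of edible portion in
#' the unit declared by the panel.
#'
#' @param panel data.frame with columns `code`, `name`, `unit`, `dri`
#'   (comma-separated subset of EAR, RDA, AI, DG, or `"none"`) and `role`
#'   (one of energy, water, macronutrient, mineral, vitamin, fatty_acid,
#'   fiber).
#' @param foods data.frame with columns `food_id` (unique), `group_id`
#'   (integer food-group number, 1-17) and `name`.
#' @param values numeric matrix, one row per food and one column per panel
#'   nutrient; `NA` marks missing entries, observed entries must be finite
#'   and non-negative.
#' @param provenance free-text source tag.
#'
#' @return An object of class `food_table` with elements `panel`, `foods`,
#'   `values` and `provenance`.
#' @export
food_table <- function(panel, foods, values, provenance = "") {
  stopifnot(is.data.frame(panel), is.data.frame(foods), is.matrix(values))
  panel <- as.data.frame(panel, stringsAsFactors = FALSE)
  required <- c("code", "name", "unit", "dri", "role")
  if (!all(required %in% names(panel)))
    stop("panel must have columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(panel$code))
    stop("duplicate nutrient codes in panel: ",
         paste(unique(panel$code[duplicated(panel$code)]), collapse = ", "))
  for (r in c("energy", "water"))
    if (sum(panel$role == r) > 1)
      stop("panel declares more than one ", r, " nutrient")
  if (anyDuplicated(foods$food_id))
    stop("duplicate food_id: ",
         paste(unique(foods$food_id[duplicated(foods$food_id)]), collapse = ", "))
  gid <- foods$group_id
  if (any(is.na(gid)) || any(gid != as.integer(gid)) || any(gid < 1L) || any(gid > 17L))
    stop("group_id must be an integer in 1..17")
  foods$group_id <- as.integer(gid)
  if (nrow(values) != nrow(foods) || ncol(values) != nrow(panel))
    stop("values must be ", nrow(foods), " x ", nrow(panel))
  obs <- values[!is.na(values)]
  if (length(obs) && (any(!is.finite(obs)) || any(obs < 0)))
    stop("observed nutrient values must be finite and non-negative")
  dimnames(values) <- list(as.character(foods$food_id), panel$code)
  structure(
    list(panel = panel, foods = foods, values = values,
         provenance = provenance),
    class = "food_table"
  )
}

#' @export
print.food_table <- function(x, ...) {
  cat("food_table:", nrow(x$foods), "foods x", nrow(x$panel), "nutrients\n")
  nmiss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(x$values)))
  cat("  groups:", paste(sort(unique(x$foods$group_id)), collapse = " "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Count foods / nutrients in a table
#'
#' @param table a [food_table()].
#' @return integer count.
#' @export
n_foods <- function(table) nrow(table$foods)

#' @rdname n_foods
#' @export
n_nutrients <- function(table) nrow(table$panel)

#' @export
dim.food_table <- function(x) c(nrow(x$foods), nrow(x$panel))

energy_code <- function(table) {
  code <- table$panel$code[table$panel$role == "energy"]
  if (length(code) != 1L) stop("table has no energy column")
  code
}

water_code <- function(table) {
  code <- table$panel$code[table$panel$role == "water"]
  if (length(code) != 1L) stop("table has no water column")
  code
}

#' Default nutrient panel
#'
#' The built-in panel mirrors the variables used for Japanese
#' food-composition analysis: energy, water, and the nutrients carrying a
#' Dietary Reference Intake category (estimated average requirement EAR,
#' recommended dietary allowance RDA, adequate intake AI, or tentative
#' dietary goal DG). Codes follow INFOODS tagnames. With
#' `include_trace = TRUE` the five sparsely-measured trace nutrients
#' (biotin, iodine, selenium, chromium, molybdenum) are appended; these
#' are the columns the ~50%-missing exclusion rule is designed to remove.
#'
#' @param include_trace logical; append the five high-missingness trace
#'   nutrients.
#' @return data.frame usable as the `panel` of a [food_table()].
#' @export
default_panel <- function(include_trace = FALSE) {
  p <- rbind(
    c("ENERC_KCAL", "Energy",                "kcal", "none",        "energy"),
    c("WATER",      "Water",                 "g",    "none",        "water"),
    c("PROT",       "Protein",               "g",    "EAR,RDA,DG",  "macronutrient"),
    c("FAT",        "Fat",                   "g",    "DG",          "macronutrient"),
    c("FASAT",      "Saturated fatty acid",  "g",    "DG",          "fatty_acid"),
    c("FAPUN3",     "n-3 PUFA",              "g",    "AI",          "fatty_acid"),
    c("FAPUN6",     "n-6 PUFA",              "g",    "AI",          "fatty_acid"),
    c("CHOCDF",     "Carbohydrate",          "g",    "DG",          "macronutrient"),
    c("FIB",        "Dietary fiber",         "g",    "DG",          "fiber"),
    c("NA",         "Sodium",                "mg",   "EAR,DG",      "mineral"),
    c("K",          "Potassium",             "mg",   "AI,DG",       "mineral"),
    c("CA",         "Calcium",               "mg",   "EAR,RDA",     "mineral"),
    c("MG",         "Magnesium",             "mg",   "EAR,RDA",     "mineral"),
    c("P",          "Phosphorus",            "mg",   "AI",          "mineral"),
    c("FE",         "Iron",                  "mg",   "EAR,RDA",     "mineral"),
    c("ZN",         "Zinc",                  "mg",   "EAR,RDA",     "mineral"),
    c("CU",         "Copper",                "mg",   "EAR,RDA",     "mineral"),
    c("MN",         "Manganese",             "mg",   "AI",          "mineral"),
    c("VITA_RAE",   "Vitamin A (RAE)",       "ug",   "EAR,RDA",     "vitamin"),
    c("VITD",       "Vitamin D",             "ug",   "AI",          "vitamin"),
    c("TOCPHA",     "Vitamin E (alpha-toc)", "mg",   "AI",          "vitamin"),
    c("VITK",       "Vitamin K",             "ug",   "AI",          "vitamin"),
    c("THIA",       "Vitamin B1",            "mg",   "EAR,RDA",     "vitamin"),
    c("RIBF",       "Vitamin B2",            "mg",   "EAR,RDA",     "vitamin"),
    c("NE",         "Niacin equivalent",     "mg",   "EAR,RDA",     "vitamin"),
    c("VITB6A",     "Vitamin B6",            "mg",   "EAR,RDA",     "vitamin"),
    c("VITB12",     "Vitamin B12",           "ug",   "EAR,RDA",     "vitamin"),
    c("FOL",        "Folic acid",            "ug",   "EAR,RDA",     "vitamin"),
    c("PANTAC",     "Pantothenic acid",      "mg",   "AI",          "vitamin"),
    c("VITC",       "Vitamin C",             "mg",   "EAR,RDA",     "vitamin")
  )
  trace <- rbind(
    c("BIOT", "Biotin",     "ug", "AI",      "vitamin"),
    c("ID",   "Iodine",     "ug", "EAR,RDA", "mineral"),
    c("SE",   "Selenium",   "ug", "EAR,RDA", "mineral"),
    c("CR",   "Chromium",   "ug", "AI",      "mineral"),
    c("MO",   "Molybdenum", "ug", "EAR,RDA", "mineral")
  )
  if (include_trace) p <- rbind(p, trace)
  out <- as.data.frame(p, stringsAsFactors = FALSE)
  names(out) <- c("code", "name", "unit", "dri", "role")
  out
}

#' Food-group names
#'
#' The 17 food groups of the Japanese Standard Tables of Food Composition
#' (prepared foods excluded), in their standard numbering.
#'
#' @return named character vector, names are the group numbers 1-17.
#' @export
group_names <- function() {
  c(`1` = "Cereals", `2` = "Potatoes and starches",
    `3` = "Sugars and sweeteners", `4` = "Pulses", `5` = "Nuts and seeds",
    `6` = "Vegetables", `7` = "Fruits", `8` = "Mushrooms", `9` = "Algae",
    `10` = "Fish, mollusks and crustaceans", `11` = "Meat", `12` = "Eggs",
    `13` = "Milk and milk products", `14` = "Fats and oils",
    `15` = "Confectionaries", `16` = "Beverages",
    `17` = "Seasonings and spices")
}

dri_categories <- function(dri_string) {
  if (is.na(dri_string) || dri_string %in% c("", "none")) return(character())
  trimws(strsplit(dri_string, ",", fixed = TRUE)[[1]])
}

#' Restrict a table to the analysis nutrient panel
#'
#' Keeps energy and water unconditionally, plus every nutrient whose
#' Dietary Reference Intake categories intersect `allowed_dri` and whose
#' missing fraction does not exceed `max_missing_fraction`. This is the
#' standard variable-selection step before imputation: DRI-relevant
#' nutrients are retained, while nutrients reported for only about half
#' of the foods (e.g. biotin, iodine, selenium, chromium, molybdenum in
#' the Japanese tables) are excluded.
#'
#' @param table a [food_table()].
#' @param allowed_dri character vector of DRI categories to keep.
#' @param max_missing_fraction nutrients missing in more than this
#'   fraction of foods are dropped (default 0.45, which removes the
#'   ~49%-missing trace panel while keeping the ~27%-missing fatty acids).
#' @return a [food_table()] with the restricted panel.
#' @export
select_nutrients <- function(table, allowed_dri = c("EAR", "RDA", "AI", "DG"),
                             max_missing_fraction = 0.45) {
  stopifnot(inherits(table, "food_table"))
  if (n_foods(table) == 0L) stop("table has no foods")
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]")
  ecode <- energy_code(table)  # errors if absent
  wcode <- water_code(table)
  miss_frac <- colMeans(is.na(table$values))
  keep <- vapply(seq_len(nrow(table$panel)), function(i) {
    code <- table$panel$code[i]
    if (code %in% c(ecode, wcode)) return(TRUE)
    cats <- dri_categories(table$panel$dri[i])
    length(intersect(cats, allowed_dri)) > 0 &&
      miss_frac[[code]] <= max_missing_fraction
  }, logical(1))
  if (!any(keep)) stop("no nutrients left after selection")
  panel <- table$panel[keep, , drop = FALSE]
  rownames(panel) <- NULL
  food_table(panel, table$foods,
             table$values[, panel$code, drop = FALSE],
             provenance = table$provenance)
}

#' Per-nutrient missingness profile
#'
#' @param table a [food_table()].
#' @return data.frame with one row per panel nutrient: `code`,
#'   `n_present` (number of foods with a reported value) and
#'   `pct_missing` (integer percentage of foods missing the nutrient).
#' @export
missingness_profile <- function(table) {
  stopifnot(inherits(table, "food_table"))
  n <- n_foods(table)
  if (n == 0L) stop("table has no foods")
  n_present <- colSums(!is.na(table$values))
  data.frame(
    code = table$panel$code,
    n_present = as.integer(n_present),
    pct_missing = as.integer(round_half_up(100 * (n - n_present) / n)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Count foods with no missing nutrient values
#'
#' @param table a [food_table()].
#' @return integer count of complete-case foods.
#' @export
complete_case_count <- function(table) {
  stopifnot(inherits(table, "food_table"))
  sum(stats::complete.cases(table$values))
}

# counts of foods per group, always over 1..17 groups present in the table
group_counts <- function(table) {
  as.integer(table(factor(table$foods$group_id,
                          levels = sort(unique(table$foods$group_id)))))
}
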