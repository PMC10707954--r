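#' Built-in group nutrient-profile centroids
#'
#' A 17-group centroid matrix emulating the structure of a national
#' food-composition table: per 100 g edible portion, each group has a
#' characteristic macronutrient dominance (carbohydrate for cereals and
#' sugars, fat for oils and nuts, protein for fish/meat/eggs) plus
#' signature micronutrient densities (e.g. vitamin K/folate/C in
#' vegetables, vitamin D and B12 in fish, sodium and iodine in algae,
#' manganese in beverages brewed from leaves). Values are the
#' log-scale means (geometric medians) of the log-normal draws in
#' [generate_table()]; energy and water are not part of the profile
#' because they are derived (Atwater identity, mass filler).
#'
#' @param include_trace also profile the five sparsely-measured trace
#'   nutrients (biotin, iodine, selenium, chromium, molybdenum).
#' @return 17 x nutrient matrix of positive centroids; rownames are the
#'   group ids, colnames the nutrient codes.
#' @export
default_profiles <- function(include_trace = FALSE) {
  codes <- c("PROT", "FAT", "FASAT", "FAPUN3", "FAPUN6", "CHOCDF", "FIB",
             "NA", "K", "CA", "MG", "P", "FE", "ZN", "CU", "MN",
             "VITA_RAE", "VITD", "TOCPHA", "VITK", "THIA", "RIBF", "NE",
             "VITB6A", "VITB12", "FOL", "PANTAC", "VITC",
             "BIOT", "ID", "SE", "CR", "MO")
  p <- rbind(
    #     PROT   FAT  FASAT FAPUN3 FAPUN6 CHOCDF  FIB    NA     K    CA    MG     P    FE   ZN    CU    MN  VITA  VITD TOCPH  VITK  THIA  RIBF    NE  B6    B12   FOL  PANT  VITC  BIOT    ID    SE   CR    MO
    `1`  = c(  8,    2,   0.5,  0.06,  0.8,    70,    4,   20,  250,   25,   70,  180,  1.5, 1.8, 0.25, 1.20,    2, 0.020,  0.8,    2, 0.25, 0.06,  3.0, 0.18, 0.010,  25, 0.70,  0.5,  4.0,   1.0,  8.0, 1.5, 40),
    `2`  = c(1.8,  0.2,  0.05,  0.01, 0.06,    20,  1.8,   10,  450,   15,   25,   55,  0.6, 0.4, 0.12, 0.20,    2, 0.010,  0.2,    2, 0.10, 0.04,  1.5, 0.20, 0.010,  25, 0.50, 25.0,  1.0,   0.5,  0.5, 1.0,  4),
    `3`  = c(0.3,  0.1,  0.02, 0.005, 0.010,   90,  0.1,   10,   30,   10,    4,    8,  0.3, 0.10,0.05, 0.10,    1, 0.005, 0.05,  0.5, 0.010,0.010, 0.10,0.010, 0.005,   2, 0.05,  0.5,  0.3,   0.3,  0.3, 0.5,  1),
    `4`  = c( 20,    9,   1.5,  0.70,  4.0,    25,   10,   15, 1100,  140,  150,  380,  4.5, 2.8, 0.80, 1.60,    3, 0.010,  2.5,   12, 0.45, 0.20,  4.5, 0.35, 0.010, 200, 1.10,  2.0, 12.0,   1.0,  5.0, 2.0,150),
    `5`  = c( 17,   50,   6.0,  1.80, 14.0,    18,  7.5,   10,  600,   90,  190,  430,  2.8, 3.2, 1.20, 2.20,    2, 0.010, 10.0,    4, 0.30, 0.15,  5.5, 0.30, 0.010,  70, 0.70,  1.5, 18.0,   0.5,  4.0, 1.2, 35),
    `6`  = c(  2, 0.25,  0.04,  0.04, 0.05,     5,  2.5,   15,  420,   60,   28,   48,  1.0, 0.45,0.09, 0.35,  120, 0.005,  1.2,   90, 0.08, 0.12,  1.0, 0.16, 0.005, 100, 0.35, 45.0,  2.5,   0.6,  0.6, 1.0, 12),
    `7`  = c(0.8, 0.25,  0.04,  0.02, 0.05,    13,  1.5,    3,  200,   18,   14,   20, 0.35, 0.15,0.06, 0.12,   25, 0.005,  0.5,    5, 0.04, 0.03,  0.5, 0.09, 0.005,  30, 0.30, 35.0,  0.8,   0.3,  0.3, 0.5,1.5),
    `8`  = c(  3,  0.4,  0.05, 0.004, 0.18,   5.5,    4,    5,  320,    2,   13,   95,  0.5, 0.7, 0.12, 0.10,  0.3, 2.000, 0.03,  0.3, 0.16, 0.22,  5.0, 0.08, 0.010,  65, 1.40,  1.0,  9.0,   0.4,  4.0, 0.6,2.5),
    `9`  = c(  9,  1.5,   0.3,  0.30, 0.15,    40,   28, 1800, 2200,  350,  400,  190,  6.0, 1.3, 0.35, 1.80,  150, 0.010,  1.8,  150, 0.20, 0.45,  3.0, 0.15, 2.500, 150, 0.55, 12.0, 11.0, 800.0,  4.0, 8.0,  9),
    `10` = c( 20,    6,   1.5,  1.40, 0.35,   0.4, 0.03,  250,  330,   35,   30,  230,  0.9, 0.9, 0.10, 0.02,   18, 7.000,  1.3,  0.3, 0.10, 0.16,  8.0, 0.30, 4.500,   9, 0.75,  1.0,  5.0,  25.0, 35.0, 1.0,  1),
    `11` = c( 18,   15,   5.5,  0.15,  1.7,   0.4, 0.03,   70,  300,    6,   21,  180,  1.3, 3.2, 0.09,0.012,   12, 0.300,  0.5,    4, 0.45, 0.20,  7.5, 0.33, 1.300,   6, 1.00,  1.0,  3.5,   1.5, 14.0, 1.0,1.2),
    `12` = c( 12,   10,   3.0,  0.10,  1.5,   0.5, 0.03,  140,  130,   50,   11,  180,  1.6, 1.3, 0.07, 0.03,  140, 2.200,  1.3,   11, 0.06, 0.40,  3.0, 0.08, 1.000,  48, 1.40,  0.3, 22.0,  25.0, 28.0, 1.0,  5),
    `13` = c(3.5,    4,   2.4,  0.03,  0.1,     5, 0.03,   45,  150,  110,   10,   95, 0.04, 0.4, 0.01, 0.01,   38, 0.300,  0.1,    2, 0.04, 0.15,  0.8, 0.03, 0.300,   5, 0.55,  1.0,  2.0,  15.0,  3.0, 0.5,  4),
    `14` = c(0.3,   95,  22.0,  2.50, 22.0,   0.5, 0.02,   15,    5,    2,    1,    3, 0.05, 0.03,0.02, 0.01,   40, 0.300, 13.0,   40, 0.010,0.010, 0.10,0.010, 0.010, 1.5, 0.05,  0.3,  0.4,   0.4,  0.4, 0.4,0.4),
    `15` = c(  6,   13,   5.5,  0.20,  1.6,    60,  1.6,  180,  140,   45,   16,   95,  0.9, 0.65,0.14, 0.35,   45, 0.400,  1.1,    5, 0.08, 0.15,  1.5, 0.06, 0.120,  16, 0.60,  1.0,  4.5,   4.0,  4.5, 1.0,  7),
    `16` = c(0.3,  0.1,  0.01, 0.003, 0.006,  3.5,  0.1,    6,   90,    4,    6,    7, 0.25, 0.06,0.025, 1.30,    3, 0.003, 0.08,    6, 0.01, 0.05,  0.3,0.035, 0.005,  14, 0.12, 12.0,  0.6,   0.4,  0.4, 0.4,0.5),
    `17` = c(  6,  3.5,   0.6,  0.20,  1.1,    20,    3, 2500,  380,   70,   65,  130,  2.2, 0.9, 0.16, 0.90,   25, 0.060,  1.2,   12, 0.07, 0.13,  2.0, 0.16, 0.060,  45, 0.45,  4.0,  7.0,   3.0,  7.0, 3.0, 18)
  )
  colnames(p) <- codes
  if (!include_trace)
    p <- p[, setdiff(codes, c("BIOT", "ID", "SE", "CR", "MO")), drop = FALSE]
  p
}

# 0/1 loadings of the four latent factors on the nutrient codes
factor_loadings <- function(codes) {
  blocks <- list(
    concentration = codes,  # dilution scales everything
    fat_soluble = c("FAT", "FASAT", "FAPUN3", "FAPUN6", "TOCPHA", "VITD",
                    "VITA_RAE", "VITK"),
    mineral = c("NA", "K", "CA", "MG", "P", "FE", "ZN", "CU", "MN",
                "ID", "SE", "CR", "MO"),
    water_vitamin = c("THIA", "RIBF", "NE", "VITB6A", "VITB12", "FOL",
                      "PANTAC", "VITC", "BIOT")
  )
  lambda <- sapply(blocks, function(b) as.numeric(codes %in% b))
  rownames(lambda) <- codes
  lambda
}

#' Default group sizes
#'
#' Per-group food counts matching the per-100 kcal column of the
#' Japanese Standard Tables analysis (total 2221), so that synthetic
#' confusion matrices have realistic row totals.
#'
#' @return integer vector of length 17.
#' @export
default_group_sizes <- function() {
  c(189L, 60L, 17L, 105L, 46L, 381L, 145L, 55L, 56L, 453L, 310L, 23L,
    58L, 31L, 176L, 23L, 93L)
}

#' Default missingness pattern
#'
#' Mirrors the missingness profile of the Japanese Standard Tables: the
#' fatty-acid panel (saturated, n-3, n-6) missing jointly for 26% of
#' foods, and per-nutrient independent missingness of 1-8% for several
#' vitamins and minerals. With `include_trace = TRUE`, the five trace
#' nutrients are additionally missing as a joint block for 49% of foods
#' — the pattern the ~50%-missing exclusion rule is designed to catch.
#'
#' @param include_trace add the 49%-missing trace-nutrient block.
#' @return list of `list(codes, rate, mode)` entries.
#' @export
default_missingness <- function(include_trace = FALSE) {
  indep <- c(VITK = 0.08, MN = 0.06, FIB = 0.04, VITD = 0.04,
             TOCPHA = 0.04, VITB12 = 0.04, VITB6A = 0.02, PANTAC = 0.02,
             VITA_RAE = 0.01, FOL = 0.01, VITC = 0.01, ZN = 0.01,
             CU = 0.01)
  out <- c(
    list(list(codes = c("FASAT", "FAPUN3", "FAPUN6"), rate = 0.26,
              mode = "block")),
    lapply(names(indep), function(code)
      list(codes = code, rate = unname(indep[code]), mode = "independent"))
  )
  if (include_trace)
    out <- c(out, list(list(codes = c("BIOT", "ID", "SE", "CR", "MO"),
                            rate = 0.49, mode = "block")))
  out
}

#' Specification for a synthetic food-composition table
#'
#' @param group_sizes foods per group (defaults to realistic 17-group
#'   counts, total 2221).
#' @param profile_centroids group x nutrient centroid matrix (defaults
#'   to [default_profiles()]).
#' @param noise_sd log-scale SD of the per-food, per-nutrient independent
#'   noise (default 0.25, i.e. roughly +/-25% scatter). This is the
#'   unrecoverable component of variation — preparation- and
#'   measurement-level scatter not shared with any other food — so
#'   imputation accuracy degrades as it grows.
#' @param item_sd log-scale SD of per-nutrient item effects (default
#'   0.1). Foods are organised as base items carrying several
#'   preparation variants, mirroring how composition tables list the
#'   same food raw, boiled, grilled or dried; variants of an item share
#'   its item effects, so this variation is recoverable from siblings.
#' @param variants_per_item average number of listed variants per base
#'   item (default 3).
#' @param factor_sds log-scale SDs of latent factors that scale
#'   correlated nutrient blocks jointly, emulating the cross-nutrient
#'   correlation of real composition tables: `concentration` (per food:
#'   dry-matter content — foods and their preparation variants range
#'   from watery to dried, moving every nutrient together on the
#'   per-100 g scale; default 1, the dominant source of within-group
#'   variation, and it cancels exactly under per-100 kcal conversion via
#'   the Atwater identity), `fat_soluble` (per item: fat and the
#'   fat-associated vitamins), `mineral` (per item: ash content), and
#'   `water_vitamin` (per item: water-soluble vitamins). Set to zeros
#'   for conditionally independent nutrients.
#' @param separation multiplier on the log-scale spread of the centroids
#'   around their across-group mean; 1 leaves the profiles as given,
#'   values below 1 pull the groups together.
#' @param missingness list of `list(codes, rate, mode)` with mode
#'   `"block"` (the whole code set missing jointly per sampled food) or
#'   `"independent"` (per cell); defaults to [default_missingness()].
#' @param include_trace include the five sparsely-measured trace
#'   nutrients (and their 49% missing block) in the panel.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(group_sizes = default_group_sizes(),
                           profile_centroids = NULL,
                           noise_sd = 0.25,
                           item_sd = 0.1,
                           variants_per_item = 3L,
                           factor_sds = c(concentration = 1,
                                          fat_soluble = 0.15,
                                          mineral = 0.1,
                                          water_vitamin = 0.1),
                           separation = 1,
                           missingness = NULL,
                           include_trace = FALSE,
                           seed = 1L) {
  profile_centroids <- profile_centroids %||% default_profiles(include_trace)
  missingness <- missingness %||% default_missingness(include_trace)
  if (length(group_sizes) != nrow(profile_centroids))
    stop("group_sizes and profile_centroids disagree on the group count")
  if (any(group_sizes < 1)) stop("group_sizes must all be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (item_sd < 0) stop("item_sd must be >= 0")
  if (variants_per_item < 1) stop("variants_per_item must be >= 1")
  if (any(factor_sds < 0)) stop("factor_sds must all be >= 0")
  factor_sds <- factor_sds[c("concentration", "fat_soluble", "mineral",
                             "water_vitamin")]
  if (anyNA(factor_sds))
    stop("factor_sds needs entries concentration, fat_soluble, mineral, ",
         "water_vitamin")
  if (any(profile_centroids <= 0))
    stop("profile centroids must be positive (log-scale means)")
  for (mspec in missingness) {
    if (mspec$rate < 0 || mspec$rate > 1) stop("missingness rates must be in [0, 1]")
    if (!mspec$mode %in% c("block", "independent"))
      stop("missingness mode must be 'block' or 'independent'")
    unknown <- setdiff(mspec$codes, colnames(profile_centroids))
    if (length(unknown))
      stop("missingness names unknown nutrient(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(n_groups = length(group_sizes),
                 group_sizes = as.integer(group_sizes),
                 profile_centroids = profile_centroids,
                 noise_sd = noise_sd, item_sd = item_sd,
                 variants_per_item = variants_per_item,
                 factor_sds = factor_sds,
                 separation = separation,
                 missingness = missingness,
                 include_trace = include_trace,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic food-composition table
#'
#' Each group's foods are organised as base items with several
#' preparation variants, the way composition tables list a food raw,
#' boiled or dried. An item's log-profile is
#' `log(centroid) + Lambda f + N(0, item_sd)`, where `f` holds the
#' item's latent factors (concentration, fat-soluble, mineral,
#' water-soluble-vitamin; see [synthetic_spec()]) and `Lambda` their 0/1
#' block loadings; each variant then adds independent per-nutrient noise
#' `N(0, noise_sd)`. The generator finally derives energy
#' from the Atwater identity `4*protein + 9*fat + 4*carbohydrate`
#' (kcal/100 g) and water as the mass filler
#' `max(0, 100 - protein - fat - carbohydrate)` (g/100 g), so that the
#' energy-macronutrient coupling that the per-100 kcal conversion relies
#' on holds exactly in the ground truth. Missingness is then applied per
#' the spec; the fully observed truth is retained alongside.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_table`: list with `table` (the [food_table()]
#'   with missing flags), `truth` (the same table fully observed) and
#'   `spec`.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  cen <- spec$profile_centroids
  logc <- log(cen)
  if (spec$separation != 1) {
    center <- colMeans(logc)
    logc <- sweep(sweep(logc, 2L, center, "-") * spec$separation,
                  2L, center, "+")
  }
  n <- sum(spec$group_sizes)
  gid <- rep(seq_len(spec$n_groups), spec$group_sizes)
  lambda <- factor_loadings(colnames(cen))
  # assign each group's foods to base items, ~variants_per_item per item
  item_of <- unlist(lapply(seq_len(spec$n_groups), function(g) {
    ng <- spec$group_sizes[g]
    n_items <- max(1L, ceiling(ng / spec$variants_per_item))
    paste0(g, "_", sort(rep_len(seq_len(n_items), ng)))
  }))
  items <- unique(item_of)
  item_group <- as.integer(sub("_.*", "", items))
  n_items <- length(items)
  # block factors at item level; concentration at food (variant) level,
  # since preparation variants (raw/boiled/dried) differ mostly in water
  f_item <- matrix(rnorm(n_items * 3L), n_items, 3L) %*%
    diag(spec$factor_sds[c("fat_soluble", "mineral", "water_vitamin")], 3L)
  item_log <- logc[item_group, , drop = FALSE] +
    f_item %*% t(lambda[, c("fat_soluble", "mineral", "water_vitamin")]) +
    matrix(rnorm(n_items * ncol(cen), sd = spec$item_sd), n_items, ncol(cen))
  rownames(item_log) <- items
  conc <- rnorm(n, sd = spec$factor_sds[["concentration"]])
  draws <- exp(item_log[item_of, , drop = FALSE] + conc +
                 matrix(rnorm(n * ncol(cen), sd = spec$noise_sd),
                        n, ncol(cen)))
  # physical cap: at most ~97 g of solids per 100 g edible portion;
  # over-concentrated draws are rescaled proportionally (dried foods sit
  # at the bound), preserving the food's density profile
  solids <- draws[, "PROT"] + draws[, "FAT"] + draws[, "CHOCDF"] +
    draws[, "FIB"]
  draws <- draws * pmin(1, 97 / solids)
  colnames(draws) <- colnames(cen)
  energy <- 4 * draws[, "PROT"] + 9 * draws[, "FAT"] + 4 * draws[, "CHOCDF"]
  water <- pmax(0, 100 - (draws[, "PROT"] + draws[, "FAT"] + draws[, "CHOCDF"]))
  cen_energy <- 4 * exp(logc[, "PROT"]) + 9 * exp(logc[, "FAT"]) +
    4 * exp(logc[, "CHOCDF"])
  if (any(cen_energy < 1))
    warning("group centroid(s) imply near-zero energy (group ",
            paste(which(cen_energy < 1), collapse = ", "),
            "); such foods exercise the density drop rule")
  panel <- default_panel(include_trace = spec$include_trace)
  panel <- panel[panel$code %in% c("ENERC_KCAL", "WATER", colnames(cen)), ,
                 drop = FALSE]
  rownames(panel) <- NULL
  values <- cbind(ENERC_KCAL = energy, WATER = water, draws)[, panel$code,
                                                            drop = FALSE]
  within <- sequence(spec$group_sizes)
  foods <- data.frame(
    food_id = sprintf("G%02d_%04d", gid, within),
    group_id = gid,
    name = sprintf("%s %d", unname(group_names()[as.character(
      ((gid - 1L) %% 17L) + 1L)]), within),
    item = item_of,
    stringsAsFactors = FALSE
  )
  truth <- food_table(panel, foods, values, provenance = "synthetic")
  masked <- values
  for (mspec in spec$missingness) {
    if (mspec$mode == "block") {
      hit <- runif(n) < mspec$rate
      masked[hit, mspec$codes] <- NA
    } else {
      for (code in mspec$codes)
        masked[runif(n) < mspec$rate, code] <- NA
    }
  }
  table <- food_table(panel, foods, masked, provenance = "synthetic")
  structure(list(table = table, truth = truth, spec = spec),
            class = "synthetic_table")
}

#' @export
print.synthetic_table <- function(x, ...) {
  cat("synthetic_table:", n_foods(x$table), "foods,",
      x$spec$n_groups, "groups, noise_sd", x$spec$noise_sd,
      ", seed", x$spec$seed, "\n")
  invisible(x)
}
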