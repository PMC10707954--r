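#' Pipeline run configuration
#'
#' A serialized `run_config`, together with the input file, fully
#' determines a pipeline run's outputs.
#'
#' @param input path to a canonical food-table CSV, or a [food_table()].
#' @param output_dir directory for stage outputs (created if needed).
#' @param seed integer seed used by every stochastic stage.
#' @param allowed_dri DRI categories kept by nutrient selection.
#' @param max_missing_fraction missingness threshold for selection.
#' @param impute an [rf_config()].
#' @param min_energy density-conversion energy floor (kcal/100 g).
#' @param perplexity,iterations t-SNE settings.
#' @param k,evaluation k-NN settings.
#' @param with_map run the t-SNE mapping stages (slowest part; disable
#'   for classification-only runs).
#' @param without_pfc also produce the variant with protein, fat and
#'   carbohydrate removed.
#' @return a `run_config` list.
#' @export
run_config <- function(input, output_dir, seed = 1L,
                       allowed_dri = c("EAR", "RDA", "AI", "DG"),
                       max_missing_fraction = 0.45,
                       impute = rf_config(),
                       min_energy = 5,
                       perplexity = 30, iterations = 1000L,
                       k = 3L, evaluation = "leave_one_out",
                       with_map = TRUE, without_pfc = TRUE) {
  if (k < 1) stop("k must be at least 1")
  if (perplexity <= 0) stop("perplexity must be positive")
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]")
  if (!evaluation %in% c("leave_one_out", "self_inclusive"))
    stop("unknown evaluation mode: ", evaluation)
  stopifnot(inherits(impute, "rf_config"))
  structure(list(input = input, output_dir = output_dir,
                 seed = as.integer(seed),
                 allowed_dri = allowed_dri,
                 max_missing_fraction = max_missing_fraction,
                 impute = impute, min_energy = min_energy,
                 perplexity = perplexity,
                 iterations = as.integer(iterations),
                 k = as.integer(k), evaluation = evaluation,
                 with_map = with_map, without_pfc = without_pfc),
            class = "run_config")
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full food-grouping pipeline
#'
#' Orchestrates ingest, nutrient selection, imputation, density
#' conversion, t-SNE mapping (all-nutrient and optionally without-PFC
#' variants) and k-NN classification, materializing every stage to disk
#' so any stage can be re-entered, and writing a machine-readable
#' manifest (files with MD5 checksums, seed, settings, per-stage counts).
#'
#' @param config a [run_config()].
#' @return a `run_report`: list with `manifest_path`, `files`, `counts`
#'   and `metrics` (macro/micro misclassification rates, map neighbour
#'   purity when mapped).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  table <- if (inherits(config$input, "food_table")) config$input
           else read_food_table(config$input)
  counts <- list(ingested = n_foods(table), nutrients_in = n_nutrients(table))
  message("ingest: ", counts$ingested, " foods x ", counts$nutrients_in,
          " nutrients")
  files <- character()

  selected <- select_nutrients(table, config$allowed_dri,
                               config$max_missing_fraction)
  counts$nutrients_selected <- n_nutrients(selected)
  message("select: ", counts$nutrients_selected, " nutrients retained")
  files["selected"] <- write_food_table(selected,
                                        file.path(config$output_dir,
                                                  "selected.csv"))
  counts$complete_cases <- complete_case_count(selected)

  imp <- fit_impute(selected, config = config$impute, seed = config$seed)
  files["completed"] <- write_food_table(imp$completed,
                                         file.path(config$output_dir,
                                                   "completed.csv"))
  files["imputation_meta"] <- write_stage_csv(imp$model_meta,
                                              config$output_dir,
                                              "imputation_meta.csv")
  message("impute: ", sum(imp$filled_mask), " cells filled")

  dens <- to_per_100kcal(imp$completed, min_energy = config$min_energy)
  counts$per_100kcal <- nrow(dens$values)
  counts$dropped_low_energy <- nrow(dens$dropped)
  message("densify: ", counts$per_100kcal, " foods per 100 kcal (",
          counts$dropped_low_energy, " dropped)")
  files["matrix"] <- write_stage_csv(
    data.frame(dens$foods, dens$values, check.names = FALSE),
    config$output_dir, "matrix.csv")

  variants <- list(all_nutrients = dens)
  if (config$without_pfc)
    variants$without_pfc <- drop_nutrients(dens, pfc_codes())

  metrics <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    if (config$with_map) {
      coords <- embed_tsne(v, perplexity = config$perplexity,
                           iterations = config$iterations,
                           seed = config$seed, variant = vn)
      files[paste0("coords_", vn)] <- write_stage_csv(
        data.frame(coords$foods, coords$xy, check.names = FALSE),
        config$output_dir, paste0("coords_", vn, ".csv"))
      files[paste0("medians_", vn)] <- write_stage_csv(
        group_medians(coords), config$output_dir,
        paste0("medians_", vn, ".csv"))
      files[paste0("effects_", vn)] <- write_stage_csv(
        nutrient_effects(coords, v), config$output_dir,
        paste0("effects_", vn, ".csv"))
      metrics[[paste0("neighbor_purity_", vn)]] <-
        neighbor_purity(coords, k = config$k)
      message("map (", vn, "): neighbour purity ",
              round(metrics[[paste0("neighbor_purity_", vn)]], 3))
    }
    cm <- knn_classify(v, k = config$k, evaluation = config$evaluation)
    mr <- misclassification_rates(cm)
    cm_df <- data.frame(group = cm$groups, cm$counts,
                        mr = mr$per_group_mr, check.names = FALSE)
    names(cm_df) <- c("group", paste0("p", cm$groups), "mr")
    files[paste0("confusion_", vn)] <- write_stage_csv(
      cm_df, config$output_dir, paste0("confusion_", vn, ".csv"))
    metrics[[paste0("macro_mr_", vn)]] <- mr$macro_mr
    metrics[[paste0("micro_mr_", vn)]] <- mr$micro_mr
    message("classify (", vn, "): macro MR ", mr$macro_mr, "%")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nutrimap")),
    seed = config$seed,
    settings = config[setdiff(names(config), c("input", "output_dir"))],
    counts = counts,
    metrics = metrics,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  structure(list(manifest_path = manifest_path, files = files,
                 counts = counts, metrics = metrics),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", length(x$files), "output files ->",
      dirname(x$manifest_path), "\n")
  for (nm in names(x$metrics))
    cat(sprintf("  %s: %.3g\n", nm, x$metrics[[nm]]))
  invisible(x)
}
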