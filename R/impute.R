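#' Imputation configuration
#'
#' Settings for the MDS + random-forest imputation and its distance step.
#'
#' @param trees number of trees per random-forest regression (default 500).
#' @param min_train minimum number of observed values a variable needs
#'   before a model is fitted for it (default 10); variables below this
#'   should be removed upstream with [select_nutrients()].
#' @param mtry predictors sampled per split; default `ceiling(K/3)`, the
#'   usual regression heuristic, where K is the MDS dimension.
#' @param mds_k MDS dimension; `NULL` (default) uses the number of panel
#'   variables M, capped at the number of foods.
#' @param standardize_distance z-score variables before the
#'   pairwise-available-case distance.
#' @param eq1_form distance rescaling form, see [pairwise_distance()].
#' @return an `rf_config` list.
#' @export
rf_config <- function(trees = 500L, min_train = 10L, mtry = NULL,
                      mds_k = NULL,
                      standardize_distance = TRUE,
                      eq1_form = c("sqrt_scaled", "linear")) {
  eq1_form <- match.arg(eq1_form)
  stopifnot(trees >= 1, min_train >= 1)
  structure(list(trees = as.integer(trees), min_train = as.integer(min_train),
                 mtry = mtry, mds_k = mds_k,
                 standardize_distance = standardize_distance,
                 eq1_form = eq1_form),
            class = "rf_config")
}

#' Impute missing nutrient values
#'
#' Four-step single-pass imputation: (1) pairwise-available-case
#' distances between all foods over the observed variables; (2) classical
#' MDS embedding of the foods to K dimensions (K = number of variables by
#' default), compressing the incomplete matrix into complete coordinates;
#' (3) for each variable with missing entries, a random-forest regression
#' of its observed values on all K MDS coordinates; (4) prediction of the
#' missing entries from the fitted forest. Predictions are clamped at 0,
#' since nutrient quantities are non-negative. Observed cells are never
#' altered. The distance matrix is not re-estimated after imputation.
#'
#' @param table a [food_table()] with missing entries.
#' @param config an [rf_config()].
#' @param seed integer seed; the result is deterministic given the seed.
#' @return an `imputation_result`: list with `completed` (a fully
#'   observed [food_table()]), `filled_mask` (logical matrix, TRUE where
#'   imputed), and `model_meta` (per-variable data.frame with training
#'   size, out-of-bag R^2, tree count and seed).
#' @export
fit_impute <- function(table, config = rf_config(), seed = 1L) {
  stopifnot(inherits(table, "food_table"), inherits(config, "rf_config"))
  if (n_foods(table) < 2L) stop("imputation needs at least 2 foods")
  x <- table$values
  miss <- is.na(x)
  n_obs <- colSums(!miss)
  short <- which(n_obs < config$min_train)
  if (length(short))
    stop("variable(s) with fewer than ", config$min_train,
         " observed values: ", paste(colnames(x)[short], collapse = ", "))
  meta <- data.frame(code = colnames(x), n_train = as.integer(n_obs),
                     n_imputed = as.integer(colSums(miss)),
                     oob_r2 = NA_real_, trees = config$trees,
                     seed = as.integer(seed), stringsAsFactors = FALSE)
  if (!any(miss)) {
    return(structure(list(completed = table, filled_mask = miss,
                          model_meta = meta, config = config,
                          seed = as.integer(seed)),
                     class = "imputation_result"))
  }
  k <- config$mds_k %||% min(ncol(x), nrow(x))
  d <- pairwise_distance(table, standardize = config$standardize_distance,
                         form = config$eq1_form)
  emb <- classical_mds(d, K = k)
  u <- as.data.frame(emb$coords)
  names(u) <- paste0("U", seq_len(ncol(u)))
  mtry <- config$mtry %||% ceiling(k / 3)
  mtry <- min(mtry, ncol(u))
  filled <- x
  for (j in seq_len(ncol(x))) {
    mj <- miss[, j]
    if (!any(mj)) next
    train <- cbind(y = x[!mj, j], u[!mj, , drop = FALSE])
    fit <- ranger::ranger(y ~ ., data = train,
                          num.trees = config$trees, mtry = mtry,
                          seed = seed + j, num.threads = 1L,
                          respect.unordered.factors = TRUE)
    pred <- predict(fit, u[mj, , drop = FALSE],
                    num.threads = 1L)$predictions
    filled[mj, j] <- pmax(pred, 0)
    meta$oob_r2[j] <- fit$r.squared
  }
  completed <- food_table(table$panel, table$foods, filled,
                          provenance = table$provenance)
  structure(list(completed = completed, filled_mask = miss,
                 model_meta = meta, config = config,
                 seed = as.integer(seed)),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("imputation_result:", sum(x$filled_mask), "cells imputed across",
      sum(colSums(x$filled_mask) > 0), "variables (seed", x$seed, ")\n")
  invisible(x)
}

#' Mask-and-recover validation of the imputation
#'
#' Measures imputation accuracy without external truth: for each
#' variable, `n_mask` observed cells are sampled uniformly (seeded) and
#' marked missing; the masked table is imputed in one pass; the Pearson
#' correlation between the withheld true values and their imputed
#' estimates is reported per variable, with the mean and range across
#' variables. A variable whose masked true values have zero variance has
#' an undefined correlation; it is excluded from the mean with a warning.
#'
#' @param table a [food_table()].
#' @param n_mask observed cells withheld per variable (default 50). With
#'   `per_variable = FALSE`, `n_mask` cells are instead sampled globally
#'   across the whole table.
#' @param seed integer seed for masking and model fitting.
#' @param config an [rf_config()].
#' @param per_variable mask per variable (default) or globally.
#' @return a `validation_report`: list with `per_variable_r` (named
#'   vector, NA where undefined), `mean_r`, `range`, `n_masked_per_variable`
#'   and `seed`.
#' @export
validate_imputation <- function(table, n_mask = 50L, seed = 1L,
                                config = rf_config(), per_variable = TRUE) {
  stopifnot(inherits(table, "food_table"))
  x <- table$values
  obs <- !is.na(x)
  set.seed(seed)
  masked <- x
  if (per_variable) {
    lack <- which(colSums(obs) < n_mask + config$min_train)
    if (length(lack))
      stop("variable(s) with fewer than n_mask + min_train = ",
           n_mask + config$min_train, " observed values: ",
           paste(colnames(x)[lack], collapse = ", "))
    for (j in seq_len(ncol(x))) {
      sel <- sample(which(obs[, j]), n_mask)
      masked[sel, j] <- NA
    }
  } else {
    pool <- which(obs)
    if (length(pool) < n_mask) stop("fewer than n_mask observed cells")
    masked[sample(pool, n_mask)] <- NA
  }
  masked_table <- food_table(table$panel, table$foods, masked,
                             provenance = table$provenance)
  res <- fit_impute(masked_table, config = config, seed = seed)
  target <- is.na(masked) & obs
  r <- vapply(seq_len(ncol(x)), function(j) {
    idx <- which(target[, j])
    if (!length(idx)) return(NA_real_)
    truth <- x[idx, j]
    if (length(unique(truth)) < 2L) return(NA_real_)
    cor(truth, res$completed$values[idx, j])
  }, numeric(1))
  names(r) <- colnames(x)
  defined <- r[!is.na(r)]
  if (!length(defined))
    stop("correlation undefined for every variable ",
         "(too few or constant masked values; increase n_mask)")
  if (anyNA(r))
    warning("correlation undefined for: ",
            paste(names(r)[is.na(r)], collapse = ", "))
  structure(list(per_variable_r = r,
                 mean_r = mean(defined),
                 range = c(min(defined), max(defined)),
                 n_masked_per_variable = if (per_variable) as.integer(n_mask)
                                         else NA_integer_,
                 seed = as.integer(seed)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "imputation validation: mean r = %.3f (range %.3f-%.3f) over %d variables\n",
    x$mean_r, x$range[1], x$range[2], sum(!is.na(x$per_variable_r))))
  invisible(x)
}
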