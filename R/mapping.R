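#' Two-dimensional t-SNE map of foods
#'
#' Embeds the per-100 kcal nutrient matrix in two dimensions with
#' t-distributed stochastic neighbor embedding, which matches
#' high-dimensional neighbour probabilities to a low-dimensional
#' Student-t kernel by minimizing the Kullback-Leibler divergence
#' between them. Nutrients are z-scored first by default so that no unit
#' dominates the similarity structure. Coordinates are reproducible for a
#' fixed seed but, like any t-SNE map, are arbitrary up to rotation and
#' reflection and differ across implementations; downstream analyses
#' should use neighbourhood structure, not raw coordinates.
#'
#' @param matrix a `nutrient_matrix` from [to_per_100kcal()].
#' @param perplexity t-SNE perplexity (effective neighbourhood size);
#'   requires at least `3 * perplexity + 1` foods.
#' @param iterations gradient-descent iterations (default 1000).
#' @param seed integer seed.
#' @param standardize z-score nutrients before embedding.
#' @param variant label recorded in the parameters, e.g.
#'   `"all_nutrients"` or `"without_pfc"`.
#' @return a `map_coordinates`: list with `foods`, `xy` (n x 2 matrix)
#'   and `params`.
#' @export
embed_tsne <- function(matrix, perplexity = 30, iterations = 1000L,
                       seed = 1L, standardize = TRUE,
                       variant = "all_nutrients") {
  stopifnot(inherits(matrix, "nutrient_matrix"))
  x <- matrix$values
  n <- nrow(x)
  if (n < 3 * perplexity + 1)
    stop("perplexity ", perplexity, " too large for n = ", n,
         " foods (need n >= 3*perplexity + 1)")
  if (any(!is.finite(x))) stop("non-finite values in nutrient matrix")
  if (standardize) {
    sigma <- apply(x, 2L, sd)
    if (any(sigma == 0))
      stop("zero-variance nutrient(s): ",
           paste(matrix$nutrients[sigma == 0], collapse = ", "))
    x <- scale(x)
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2L, perplexity = perplexity,
                      max_iter = as.integer(iterations), theta = 0.5,
                      pca = TRUE, check_duplicates = FALSE,
                      normalize = FALSE, verbose = FALSE)
  xy <- fit$Y
  dimnames(xy) <- list(matrix$foods$food_id, c("x", "y"))
  structure(list(foods = matrix$foods, xy = xy,
                 params = list(perplexity = perplexity,
                               iterations = as.integer(iterations),
                               seed = as.integer(seed),
                               standardized = standardize,
                               variant = variant)),
            class = "map_coordinates")
}

#' @export
print.map_coordinates <- function(x, ...) {
  cat("map_coordinates:", nrow(x$xy), "foods (variant ",
      x$params$variant, ", perplexity ", x$params$perplexity, ", seed ",
      x$params$seed, ")\n", sep = "")
  invisible(x)
}

#' Componentwise group medians on the map
#'
#' The per-group marker positions drawn on food maps: for each food
#' group, the componentwise median of its members' map coordinates
#' (even counts: mean of the two middle values).
#'
#' @param coords a `map_coordinates`.
#' @return data.frame with `group_id`, `x`, `y`, one row per non-empty
#'   group, ordered by group.
#' @export
group_medians <- function(coords) {
  stopifnot(inherits(coords, "map_coordinates"))
  gid <- coords$foods$group_id
  if (anyNA(gid)) stop("every food needs a group_id")
  groups <- sort(unique(gid))
  out <- data.frame(
    group_id = groups,
    x = vapply(groups, function(g) median(coords$xy[gid == g, 1L]), numeric(1)),
    y = vapply(groups, function(g) median(coords$xy[gid == g, 2L]), numeric(1))
  )
  out
}

#' Nutrient-effect overlay coordinates
#'
#' Places each nutrient on the map at the value-weighted centroid of the
#' foods dense in it: weights are the positive part of the nutrient's
#' per-food z-score, \eqn{w_i = \max(z_{ij}, 0)}, and the overlay
#' coordinate is \eqn{\sum_i w_i \mathbf{y}_i / \sum_i w_i}. This is a
#' transparent reconstruction of the usual "nutrient effect" annotation
#' on food maps: a nutrient is pulled toward the region of the map whose
#' foods carry above-average densities of it.
#'
#' @param coords a `map_coordinates`.
#' @param matrix the `nutrient_matrix` the map was built from (same foods,
#'   same order).
#' @return data.frame with `code`, `x`, `y`, one row per nutrient.
#' @export
nutrient_effects <- function(coords, matrix) {
  stopifnot(inherits(coords, "map_coordinates"),
            inherits(matrix, "nutrient_matrix"))
  if (!identical(as.character(coords$foods$food_id),
                 as.character(matrix$foods$food_id)))
    stop("coords and matrix must cover the same foods in the same order")
  z <- scale(matrix$values)
  bad <- which(!is.finite(colSums(z)))
  if (length(bad))
    stop("zero-variance nutrient(s): ",
         paste(matrix$nutrients[bad], collapse = ", "))
  w <- pmax(z, 0)
  tot <- colSums(w)
  if (any(tot == 0))
    stop("all-zero weights for nutrient(s): ",
         paste(matrix$nutrients[tot == 0], collapse = ", "))
  data.frame(code = matrix$nutrients,
             x = colSums(w * coords$xy[, 1L]) / tot,
             y = colSums(w * coords$xy[, 2L]) / tot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Same-group purity of map neighbourhoods
#'
#' Quality metric for a map: the fraction, over all foods, of each
#' food's k nearest map-space neighbours (itself excluded) that belong
#' to the food's own group. Values near 1 indicate that the 2D map
#' preserves the group structure of the nutrient space.
#'
#' @param coords a `map_coordinates`.
#' @param k neighbours per food (default 3).
#' @return a single number in [0, 1].
#' @export
neighbor_purity <- function(coords, k = 3L) {
  stopifnot(inherits(coords, "map_coordinates"))
  n <- nrow(coords$xy)
  if (k >= n) stop("k must be smaller than the number of foods")
  d <- as.matrix(dist(coords$xy))
  gid <- coords$foods$group_id
  same <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, -i])
    nb <- seq_len(n)[-i][ord[seq_len(k)]]
    mean(gid[nb] == gid[i])
  }, numeric(1))
  mean(same)
}
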