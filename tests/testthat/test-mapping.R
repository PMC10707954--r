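map_fixture <- function(n_per_group = 50, seed = 21) {
  st <- generate_table(small_synthetic(n_per_group = n_per_group, seed = seed))
  to_per_100kcal(fit_impute(st$table, rf_config(trees = 100),
                            seed = seed)$completed)
}

test_that("t-SNE is deterministic for a fixed seed and separates clear groups", {
  nm <- map_fixture()
  a <- embed_tsne(nm, perplexity = 12, iterations = 400, seed = 3)
  b <- embed_tsne(nm, perplexity = 12, iterations = 400, seed = 3)
  expect_identical(a$xy, b$xy)
  # three well-separated groups: almost all map neighbours stay in-group
  expect_gte(neighbor_purity(a, k = 3), 0.95)
})

test_that("near-duplicate foods end up as mutual nearest map neighbours", {
  nm <- map_fixture(n_per_group = 25, seed = 22)
  dup <- nm
  n <- nrow(nm$values)
  set.seed(1)
  dup$values <- rbind(nm$values, nm$values * (1 + 1e-9))
  dup$foods <- rbind(nm$foods, transform(nm$foods,
                                         food_id = paste0(food_id, "_b")))
  co <- embed_tsne(dup, perplexity = 10, iterations = 400, seed = 4)
  d <- as.matrix(dist(co$xy)); diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  frac_paired <- mean(nn[seq_len(n)] == seq_len(n) + n &
                        nn[seq_len(n) + n] == seq_len(n))
  expect_gte(frac_paired, 0.95)
})

test_that("perplexity beyond the solver's limit is rejected", {
  nm <- map_fixture(n_per_group = 10, seed = 23)
  expect_error(embed_tsne(nm, perplexity = 30), "perplexity")
})

test_that("group medians use the componentwise median with the even-count convention", {
  xy <- rbind(c(3, -7), c(0, 0), c(2, 0), c(10, 4), c(1, 1), c(3, 5))
  coords <- structure(list(
    foods = data.frame(food_id = paste0("f", 1:6),
                       group_id = c(2L, 1L, 1L, 1L, 3L, 3L),
                       name = paste0("f", 1:6)),
    xy = xy, params = list(variant = "test")), class = "map_coordinates")
  med <- group_medians(coords)
  expect_equal(med$x[med$group_id == 2], 3)    # singleton group
  expect_equal(med$y[med$group_id == 2], -7)
  expect_equal(med$x[med$group_id == 1], 2)    # odd count picks middle
  expect_equal(med$y[med$group_id == 3], 3)    # even count averages middle two
  # oracle comparison on a larger random group
  set.seed(2)
  big <- structure(list(
    foods = data.frame(food_id = paste0("g", 1:100), group_id = 1L,
                       name = paste0("g", 1:100)),
    xy = matrix(rnorm(200), 100, 2), params = list(variant = "test")),
    class = "map_coordinates")
  mb <- group_medians(big)
  expect_equal(mb$x, median(big$xy[, 1]))
  expect_equal(mb$y, median(big$xy[, 2]))
})

test_that("nutrient effects sit at the positive-z weighted centroid of food positions", {
  nm <- map_fixture(n_per_group = 20, seed = 24)
  co <- embed_tsne(nm, perplexity = 8, iterations = 300, seed = 5)
  eff <- nutrient_effects(co, nm)
  # nested-loop oracle
  z <- scale(nm$values)
  for (j in sample(length(nm$nutrients), 5)) {
    w <- pmax(z[, j], 0)
    expect_equal(eff$x[j], sum(w * co$xy[, 1]) / sum(w), tolerance = 1e-12)
    expect_equal(eff$y[j], sum(w * co$xy[, 2]) / sum(w), tolerance = 1e-12)
  }
  # a nutrient concentrated in one food lands on that food
  single <- nm
  single$values <- cbind(nm$values, SPIKE = c(5, rep(1e-3, nrow(nm$values) - 1)))
  single$nutrients <- c(nm$nutrients, "SPIKE")
  eff2 <- nutrient_effects(co, single)
  expect_equal(eff2$x[eff2$code == "SPIKE"], co$xy[1, 1], tolerance = 1e-6)
  # identical z-patterns give identical overlay coordinates
  twin <- nm
  twin$values <- cbind(nm$values, TWIN = nm$values[, 1] * 1000)
  twin$nutrients <- c(nm$nutrients, "TWIN")
  eff3 <- nutrient_effects(co, twin)
  expect_equal(eff3[eff3$code == "TWIN", c("x", "y")],
               eff3[eff3$code == nm$nutrients[1], c("x", "y")],
               ignore_attr = TRUE)
})

test_that("medians and effects shift with a global translation of the map", {
  nm <- map_fixture(n_per_group = 15, seed = 25)
  co <- embed_tsne(nm, perplexity = 6, iterations = 300, seed = 6)
  shifted <- co
  shifted$xy <- co$xy + matrix(c(5, -3), nrow(co$xy), 2, byrow = TRUE)
  expect_equal(group_medians(shifted)$x, group_medians(co)$x + 5)
  expect_equal(group_medians(shifted)$y, group_medians(co)$y - 3)
  expect_equal(nutrient_effects(shifted, nm)$x, nutrient_effects(co, nm)$x + 5)
})

test_that("mismatched inputs and degenerate nutrients are rejected", {
  nm <- map_fixture(n_per_group = 12, seed = 26)
  co <- embed_tsne(nm, perplexity = 5, iterations = 250, seed = 7)
  other <- nm
  other$foods <- nm$foods[rev(seq_len(nrow(nm$foods))), ]
  expect_error(nutrient_effects(co, other), "same foods")
  flat <- nm
  flat$values[, 2] <- 1
  expect_error(nutrient_effects(co, flat), "zero-variance")
})
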