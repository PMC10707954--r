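# one-column nutrient matrix for hand-checkable geometry
line_matrix <- function(x, groups) {
  structure(list(
    foods = data.frame(food_id = paste0("f", seq_along(x)),
                       group_id = groups, name = paste0("f", seq_along(x))),
    nutrients = "N1",
    values = matrix(x, ncol = 1, dimnames = list(NULL, "N1")),
    dropped = data.frame(), min_energy = 0), class = "nutrient_matrix")
}

test_that("leave-one-out 3-NN classifies two tight clusters on a line perfectly", {
  nm <- line_matrix(c(0, 1, 2, 10, 11, 12), c(1L, 1L, 1L, 2L, 2L, 2L))
  cm <- knn_classify(nm, k = 3, standardize = FALSE)
  expect_identical(unname(diag(cm$counts)), c(3L, 3L))
  expect_identical(sum(cm$counts) , 6L)
  mr <- misclassification_rates(cm)
  expect_identical(unname(mr$per_group_mr), c(0L, 0L))
})

test_that("well-separated synthetic groups classify without error", {
  st <- generate_table(small_synthetic(n_per_group = 20, seed = 31))
  nm <- to_per_100kcal(fit_impute(st$table, rf_config(trees = 100),
                                  seed = 31)$completed)
  cm <- knn_classify(nm, k = 3)
  expect_identical(unname(diag(cm$counts)), unname(cm$row_totals))
  # k = 1 with coherent clusters is also error-free
  cm1 <- knn_classify(nm, k = 1)
  expect_identical(sum(cm1$counts) - sum(diag(cm1$counts)), 0L)
})

test_that("confusion counts are conserved and permutation invariant", {
  st <- generate_table(small_synthetic(n_per_group = 15, noise_sd = 0.6,
                                       seed = 32))
  nm <- to_per_100kcal(fit_impute(st$table, rf_config(trees = 80),
                                  seed = 32)$completed)
  cm <- knn_classify(nm, k = 3)
  sizes <- table(nm$foods$group_id)
  expect_identical(unname(cm$row_totals), as.integer(sizes))
  expect_identical(sum(cm$counts), nrow(nm$values))
  perm <- sample(nrow(nm$values))
  shuffled <- nm
  shuffled$foods <- nm$foods[perm, ]
  shuffled$values <- nm$values[perm, , drop = FALSE]
  expect_identical(knn_classify(shuffled, k = 3)$counts, cm$counts)
})

test_that("standardized distances ignore a nutrient's unit scale", {
  st <- generate_table(small_synthetic(n_per_group = 15, noise_sd = 0.5,
                                       seed = 33))
  nm <- to_per_100kcal(fit_impute(st$table, rf_config(trees = 80),
                                  seed = 33)$completed)
  rescaled <- nm
  rescaled$values[, "FE"] <- rescaled$values[, "FE"] * 1000
  expect_identical(knn_classify(rescaled, k = 3)$counts,
                   knn_classify(nm, k = 3)$counts)
})

test_that("1-1-1 vote ties go to the nearest neighbour's group", {
  # food f1 at 0; nearest neighbours at 1 (group 2), 2 (group 3), 3 (group 1)
  nm <- line_matrix(c(0, 1, 2, 3, 10, 11, 12), c(1L, 2L, 3L, 1L, 2L, 3L, 1L))
  cm <- knn_classify(nm, k = 3, standardize = FALSE)
  expect_identical(unname(cm$counts["1", "2"]), 1L)  # f1 predicted group 2
})

test_that("k-NN agrees with class::knn.cv on tie-free data", {
  skip_if_not_installed("class")
  st <- generate_table(small_synthetic(n_per_group = 25, noise_sd = 0.5,
                                       seed = 34))
  nm <- to_per_100kcal(fit_impute(st$table, rf_config(trees = 80),
                                  seed = 34)$completed)
  z <- scale(nm$values)
  ours <- knn_classify(nm, k = 1)  # k = 1 cannot tie (distinct distances)
  ref <- class::knn.cv(z, factor(nm$foods$group_id), k = 1)
  ref_cm <- table(factor(nm$foods$group_id), ref)
  expect_identical(unname(cm <- ours$counts), unname(matrix(as.integer(ref_cm),
                                                            nrow(ref_cm))))
})

test_that("misclassification rates round half up and average over groups", {
  counts <- diag(c(96, 46, 17))
  counts[1, 2] <- 4    # 4/100 -> 4%
  counts[2, 3] <- 4    # 4/50 -> 8%
  counts[3, 1] <- 17   # 17/34 -> 50%
  cm <- as_confusion_matrix(counts)
  mr <- misclassification_rates(cm)
  expect_identical(unname(mr$per_group_mr), c(4L, 8L, 50L))
  expect_identical(mr$macro_mr, 21L)  # mean 20.67 rounds up
  expect_equal(mr$micro_mr, 100 * 25 / 184)
  # the half-up convention: 23.5% prints as 24
  half <- as_confusion_matrix(rbind(c(13, 4), c(0, 17)))
  expect_identical(unname(misclassification_rates(half)$per_group_mr[1]), 24L)
  # identity matrix scores zero everywhere
  ident <- misclassification_rates(as_confusion_matrix(diag(3L) * 5L))
  expect_true(all(ident$per_group_mr == 0L) && ident$macro_mr == 0L)
  # empty rows are invalid
  bad <- as_confusion_matrix(rbind(c(2, 0), c(0, 0)))
  expect_error(misclassification_rates(bad), "empty row")
})

test_that("single-food queries report the vote and its neighbours", {
  st <- generate_table(small_synthetic(n_per_group = 20, seed = 35))
  nm <- to_per_100kcal(fit_impute(st$table, rf_config(trees = 80),
                                  seed = 35)$completed)
  # a synthetic beverage built as a scaled copy of a vegetable profile
  veg <- nm$values[nm$foods$group_id == 2, , drop = FALSE]  # group 6 -> idx 2
  probe <- colMeans(veg) * 1.001
  q_nm <- nm
  q_nm$values <- rbind(nm$values, probe)
  probe_row <- nm$foods[1, ]
  probe_row$food_id <- "beverage_probe"
  probe_row$group_id <- 16L
  probe_row$name <- "tea-like probe"
  q_nm$foods <- rbind(nm$foods, probe_row)
  q <- nearest_group_query(q_nm, "beverage_probe", k = 3)
  expect_identical(q$predicted_group, 2L)
  expect_identical(nrow(q$neighbors), 3L)
  expect_true(all(diff(q$neighbors$distance) >= 0))
  # an exact jittered duplicate is claimed by its twin at k = 1
  dup_nm <- nm
  dup_nm$values <- rbind(nm$values, nm$values[7, ] * (1 + 1e-9))
  dup_row <- nm$foods[7, ]
  dup_row$food_id <- "dup"
  dup_row$group_id <- 16L
  dup_nm$foods <- rbind(nm$foods, dup_row)
  qd <- nearest_group_query(dup_nm, "dup", k = 1)
  expect_identical(qd$predicted_group, nm$foods$group_id[7])
  expect_identical(qd$neighbors$food_id[1], nm$foods$food_id[7])
  expect_error(nearest_group_query(nm, "nope", k = 3), "unknown food_id")
  expect_error(nearest_group_query(nm, nm$foods$food_id[1],
                                   k = nrow(nm$values)), "smaller")
})
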