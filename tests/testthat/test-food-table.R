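test_that("missing-value dialect resolves markers the way source tables use them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "food_id,group_id,name,PROT,FIB,VITC",
    "a,1,rice,6.1,-,Tr",
    "b,6,spinach,(2.2),2.8,35",
    "c,6,kale,2.9,,(Tr)"
  ), path)
  ft <- read_food_table(path, panel = default_panel())
  expect_equal(dim(ft), c(3L, 3L))
  expect_true(is.na(ft$values["a", "FIB"]))        # "-" is not measured
  expect_identical(ft$values["a", "VITC"], 0)      # trace reads as 0
  expect_identical(ft$values["b", "PROT"], 2.2)    # estimate "(x)" reads as x
  expect_true(is.na(ft$values["c", "FIB"]))        # blank cell
  expect_identical(ft$values["c", "VITC"], 0)      # "(Tr)" is an estimated trace

  strict <- read_food_table(path, panel = default_panel(),
                            dialect = missing_dialect(parenthesized = "missing"))
  expect_true(is.na(strict$values["b", "PROT"]))
})

test_that("a clean table reads with all values present", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("food_id,group_id,name,PROT,FAT",
               "a,1,x,1.5,2", "b,2,y,3,4.25"), path)
  ft <- read_food_table(path, panel = default_panel())
  expect_equal(dim(ft), c(2L, 2L))
  expect_false(anyNA(ft$values))
})

test_that("malformed inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("food_id,group_id,PROT", "a,1,abc", "b,1,2"), path)
  expect_error(read_food_table(path, panel = default_panel()),
               "row 1, column 'PROT'")
  writeLines(c("food_id,group_id,PROT", "a,fish,1"), path)
  expect_error(read_food_table(path, panel = default_panel()),
               "unknown group label")
  writeLines(c("food_id,group_id,PROT", "a,1,1", "a,2,2"), path)
  expect_error(read_food_table(path, panel = default_panel()),
               "duplicate food_id")
})

test_that("column maps translate source headers to panel codes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,grp,protein_g", "a,3,7.5"), path)
  ft <- read_food_table(path, panel = default_panel(),
                        column_map = c(id = "food_id", grp = "group_id",
                                       protein_g = "PROT"))
  expect_identical(unname(ft$values[1, "PROT"]), 7.5)
  expect_identical(ft$foods$group_id, 3L)
})

test_that("write/read round-trips a table bit-identically", {
  st <- generate_table(small_synthetic(n_per_group = 8, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_table(st$table, path)
  back <- read_food_table(path, panel = st$table$panel)
  expect_identical(back$values, st$table$values)
  expect_identical(is.na(back$values), is.na(st$table$values))
  expect_identical(back$foods$group_id, st$table$foods$group_id)
})

test_that("nutrient selection drops sparse nutrients, keeps energy and water, and is idempotent", {
  st <- generate_table(synthetic_spec(group_sizes = rep(40, 3),
                                      profile_centroids =
                                        default_profiles(TRUE)[c(1, 6, 10), ],
                                      include_trace = TRUE, seed = 2))
  expect_equal(n_nutrients(st$table), 35L)
  sel <- select_nutrients(st$table, max_missing_fraction = 0.45)
  expect_equal(n_nutrients(sel), 30L)
  expect_false(any(c("BIOT", "ID", "SE", "CR", "MO") %in% sel$panel$code))
  expect_true(all(c("ENERC_KCAL", "WATER") %in% sel$panel$code))
  again <- select_nutrients(sel, max_missing_fraction = 0.45)
  expect_identical(again$panel, sel$panel)

  # a single 60%-missing nutrient is dropped, the rest are kept
  tab <- make_table(matrix(rexp(200), 20, 10))
  vals <- tab$values
  vals[1:12, 4] <- NA
  tab2 <- food_table(tab$panel, tab$foods, vals)
  tab2$panel$role[1:2] <- c("energy", "water")  # satisfy selection precondition
  sel2 <- select_nutrients(tab2, allowed_dri = "EAR",
                           max_missing_fraction = 0.45)
  expect_identical(setdiff(tab2$panel$code, sel2$panel$code), "N4")

  # with nothing missing and a zero threshold everything survives
  tab3 <- food_table(tab2$panel, tab$foods, tab$values)
  sel3 <- select_nutrients(tab3, allowed_dri = "EAR",
                           max_missing_fraction = 0)
  expect_equal(n_nutrients(sel3), 10L)
})

test_that("missingness profile counts and percentages are consistent", {
  x <- matrix(rexp(50), 10, 5)
  x[1:3, 2] <- NA
  tab <- make_table(x)
  prof <- missingness_profile(tab)
  expect_identical(prof$n_present[2], 7L)
  expect_identical(prof$pct_missing[2], 30L)
  expect_identical(prof$pct_missing[1], 0L)
  # percentage recomputes the missing count within rounding
  expect_true(all(abs((10 - prof$n_present) - prof$pct_missing * 10 / 100) <= 0.5))

  full <- make_table(matrix(1:20 + 0.5, 4, 5))
  expect_true(all(missingness_profile(full)$pct_missing == 0L))
})

test_that("complete-case counting matches direct row inspection", {
  x <- matrix(rexp(60), 12, 5)
  tab <- make_table(x)
  expect_identical(complete_case_count(tab), 12L)
  x[7, 3] <- NA
  expect_identical(complete_case_count(make_table(x)), 11L)
})

test_that("food_table validates its invariants", {
  x <- matrix(1:6 + 0.5, 2, 3)
  tab <- make_table(x)
  expect_error(food_table(tab$panel,
                          data.frame(food_id = c("a", "a"),
                                     group_id = c(1L, 2L), name = c("a", "b")),
                          x), "duplicate food_id")
  expect_error(food_table(tab$panel,
                          data.frame(food_id = c("a", "b"),
                                     group_id = c(0L, 2L), name = c("a", "b")),
                          x), "group_id")
  x[1, 1] <- -1
  expect_error(make_table(x), "non-negative")
})
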