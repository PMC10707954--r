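# small builders used across tests

# generic food_table from a numeric matrix; panel roles are generic
# macronutrients unless energy/water columns are requested
make_table <- function(values, group_id = 1L, energy_water = FALSE) {
  values <- as.matrix(values)
  m <- ncol(values)
  codes <- paste0("N", seq_len(m))
  roles <- rep("macronutrient", m)
  if (energy_water) {
    codes[1:2] <- c("ENERC_KCAL", "WATER")
    roles[1:2] <- c("energy", "water")
  }
  panel <- data.frame(code = codes, name = codes, unit = "g",
                      dri = "EAR", role = roles,
                      stringsAsFactors = FALSE)
  panel$dri[roles %in% c("energy", "water")] <- "none"
  n <- nrow(values)
  foods <- data.frame(food_id = paste0("f", seq_len(n)),
                      group_id = rep_len(group_id, n),
                      name = paste0("food ", seq_len(n)),
                      stringsAsFactors = FALSE)
  food_table(panel, foods, values)
}

# three well-separated groups drawn from distinct real-profile centroids
small_synthetic <- function(n_per_group = 40, noise_sd = 0.2, seed = 1,
                            groups = c(1, 6, 10), ...) {
  synthetic_spec(group_sizes = rep(n_per_group, length(groups)),
                 profile_centroids = default_profiles()[groups, , drop = FALSE],
                 noise_sd = noise_sd, seed = seed, ...)
}

# brute-force pairwise-available-case distance oracle
pac_oracle <- function(x, m = ncol(x), standardize = FALSE,
                       form = "sqrt_scaled") {
  if (standardize) {
    mu <- colMeans(x, na.rm = TRUE)
    sg <- apply(x, 2, sd, na.rm = TRUE)
    x <- sweep(sweep(x, 2, mu, "-"), 2, sg, "/")
  }
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    sh <- which(!is.na(x[i, ]) & !is.na(x[k, ]))
    s <- sum((x[i, sh] - x[k, sh])^2)
    d[i, k] <- if (form == "sqrt_scaled") sqrt(m / length(sh) * s)
               else m / length(sh) * sqrt(s)
  }
  d
}

# random incomplete table guaranteed to have all pairs sharing a column
random_missing_table <- function(n, m, miss = 0.2) {
  x <- matrix(rexp(n * m), n, m)
  x[matrix(runif(n * m) < miss, n, m)] <- NA
  x[, 1] <- rexp(n)  # anchor column keeps every pair comparable
  make_table(x)
}
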