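#' Pairwise-available-case distance matrix
#'
#' Computes distances between foods from incomplete data: for each pair
#' of foods the squared differences are summed over the variables
#' observed in both, and the sum is rescaled to the full variable count
#' before taking the square root,
#' \deqn{d_{ii'} = \sqrt{(M/U_{ii'}) \sum_{j \in O_{ii'}} (x_{ij} - x_{i'j})^2},}
#' where \eqn{M} is the number of variables, \eqn{O_{ii'}} the set of
#' variables observed in both foods and \eqn{U_{ii'} = |O_{ii'}|}. On
#' complete data this reduces exactly to the Euclidean distance. The
#' alternative `form = "linear"` applies the \eqn{M/U} factor to the
#' partial distance itself rather than to its square.
#'
#' Because nutrients span units from micrograms to grams, variables are
#' by default z-scored (mean and SD over their observed entries) before
#' differencing; set `standardize = FALSE` for raw-unit distances.
#'
#' @param table a [food_table()].
#' @param standardize z-score each variable over observed entries first.
#' @param form `"sqrt_scaled"` (default; rescales the squared partial
#'   distance) or `"linear"` (rescales the partial distance).
#' @return a `pac_dist` object: list with `n`, symmetric matrix `d`,
#'   matrix `u_counts` of shared-observed-variable counts, and `m` (the
#'   variable count).
#' @export
pairwise_distance <- function(table, standardize = TRUE,
                              form = c("sqrt_scaled", "linear")) {
  stopifnot(inherits(table, "food_table"))
  form <- match.arg(form)
  x <- table$values
  n <- nrow(x)
  m <- ncol(x)
  w <- !is.na(x)
  if (standardize) {
    mu <- colMeans(x, na.rm = TRUE)
    sigma <- apply(x, 2L, sd, na.rm = TRUE)
    zero <- which(!is.finite(sigma) | sigma == 0)
    if (length(zero))
      stop("zero variance among observed values for variable(s): ",
           paste(colnames(x)[zero], collapse = ", "))
    x <- sweep(sweep(x, 2L, mu, "-"), 2L, sigma, "/")
  }
  x0 <- x
  x0[!w] <- 0
  wm <- matrix(as.numeric(w), n, m)
  u <- wm %*% t(wm)
  if (n > 1L) {
    uo <- u
    diag(uo) <- 1
    if (any(uo < 1)) {
      bad <- which(uo < 1, arr.ind = TRUE)[1L, ]
      stop("foods '", rownames(x)[bad[1L]], "' and '", rownames(x)[bad[2L]],
           "' share no observed variable")
    }
  }
  sq <- x0^2
  a <- sq %*% t(wm)
  s <- a + t(a) - 2 * x0 %*% t(x0)
  s[s < 0] <- 0  # numerical noise from the cross-product expansion
  d <- if (form == "sqrt_scaled") sqrt((m / u) * s) else (m / u) * sqrt(s)
  diag(d) <- 0
  d <- (d + t(d)) / 2  # enforce exact symmetry
  dimnames(d) <- dimnames(u) <- list(rownames(x), rownames(x))
  structure(list(n = n, d = d, u_counts = u, m = m,
                 standardize = standardize, form = form),
            class = "pac_dist")
}

#' @export
print.pac_dist <- function(x, ...) {
  cat("pairwise-available-case distances:", x$n, "foods,", x$m,
      "variables (", x$form, if (x$standardize) ", standardized" else "",
      ")\n", sep = "")
  invisible(x)
}
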