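#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds the objects of a distance matrix in K-dimensional Euclidean
#' space by double-centering the squared distances,
#' \eqn{B = -\frac{1}{2} J D^{(2)} J} with \eqn{J = I - \frac{1}{n} 11'},
#' followed by a symmetric eigendecomposition. Coordinates are the
#' eigenvectors scaled by the square roots of their eigenvalues, ordered
#' by decreasing eigenvalue. Because a pairwise-available-case distance
#' matrix need not be Euclidean, negative eigenvalues can occur; the
#' corresponding axes are returned as zero-filled columns so that the
#' embedding always has exactly K columns. Each column's sign is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param D a `pac_dist` from [pairwise_distance()], a `dist`, or a
#'   symmetric numeric matrix of distances.
#' @param K embedding dimension, between 1 and n.
#' @return an `mds_embedding`: list with `coords` (n x K matrix),
#'   `eigenvalues` (the K retained eigenvalues, non-increasing, negative
#'   ones reported as found but their axes zeroed) and `K`.
#' @export
classical_mds <- function(D, K) {
  d <- if (inherits(D, "pac_dist")) D$d else as.matrix(D)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
    stop("distance matrix is not symmetric")
  if (K < 1 || K > n) stop("K must be between 1 and n = ", n)
  d2 <- d^2
  # double-center: B = -1/2 J d2 J without forming J
  rm_ <- rowMeans(d2)
  b <- -0.5 * (d2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(d2))
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  if (all(e$values <= 1e-12 * max(abs(e$values), 1)))
    stop("degenerate distance matrix: no positive eigenvalue")
  lambda <- e$values[seq_len(K)]
  coords <- matrix(0, n, K)
  pos <- lambda > 0
  coords[, pos] <- e$vectors[, which(pos), drop = FALSE] %*%
    diag(sqrt(lambda[pos]), sum(pos))
  # sign convention: largest-magnitude loading positive
  for (k in which(pos)) {
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("MDS", seq_len(K))
  structure(list(coords = coords, eigenvalues = lambda, K = K),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("classical MDS embedding:", nrow(x$coords), "objects in", x$K,
      "dimensions\n")
  npos <- sum(x$eigenvalues > 0)
  cat("  positive eigenvalues among retained:", npos, "\n")
  invisible(x)
}
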