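# Lloyd's k-means with greedy farthest-point seeding.
#
# The clustering stage is central to the bag-of-features encoding, so it is
# implemented here with an inspectable objective trace: centroids are the
# means of their assigned vectors and every vector is assigned to its
# nearest centroid (squared Euclidean), ties to the lowest index.

# squared Euclidean distances, n x k
sqdist <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  pmax(d2, 0)
}

#' k-means clustering (Lloyd's algorithm)
#'
#' Initialization is greedy spread-maximizing: a seeded random first
#' centroid, then repeatedly the point farthest from the chosen set.
#' Iteration stops when the relative centroid movement drops below `tol`
#' or after `max_iter` sweeps. The within-cluster sum-of-squares objective
#' is recorded per iteration (it is non-increasing).
#'
#' @param X Numeric matrix, observations in rows.
#' @param k Number of clusters (`<= nrow(X)`).
#' @param seed Integer seed (initialization only; the rest is deterministic).
#' @param max_iter,tol Convergence controls.
#' @return List with `centers` (k x d), `assignment` (1-based), `objective`
#'   (per-iteration trace) and `iterations`.
#' @export
kmeans_lloyd <- function(X, k, seed = 1L, max_iter = 300L, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop(sprintf("k = %d exceeds the number of vectors (%d)", k, n))
  centers <- with_seed(seed, {
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    if (k > 1L) {
      dmin <- sqdist(X, X[idx[1L], , drop = FALSE])[, 1L]
      for (j in 2:k) {
        idx[j] <- which.max(dmin)
        dmin <- pmin(dmin, sqdist(X, X[idx[j], , drop = FALSE])[, 1L])
      }
    }
    X[idx, , drop = FALSE]
  })
  obj <- numeric(0)
  assign <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    obj <- c(obj, sum(d2[cbind(seq_len(n), assign)]))
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        # empty cluster: grab the point currently worst represented
        new_centers[j, ] <- X[which.max(d2[cbind(seq_len(n), assign)]), ]
      }
    }
    move <- sqrt(max(rowSums((new_centers - centers)^2))) /
      (sqrt(max(rowSums(centers^2))) + 1e-12)
    centers <- new_centers
    if (move < tol) break
  }
  # final assignment consistent with returned centers
  d2 <- sqdist(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  obj <- c(obj, sum(d2[cbind(seq_len(n), assign)]))
  list(centers = centers, assignment = assign, objective = obj, iterations = it)
}
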