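#' @keywords internal
#' Validate an observations-by-features numeric matrix.
#' Accepts a matrix or data frame; returns a plain numeric matrix.
as_data_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix or data frame (rows = observations, ",
         "columns = features)", call. = FALSE)
  if (nrow(x) < 2L) stop("`x` must have at least 2 rows", call. = FALSE)
  if (ncol(x) < 1L) stop("`x` must have at least 1 column", call. = FALSE)
  if (!all(is.finite(x))) stop("all entries of `x` must be finite", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Sample initial centroids for Lloyd's algorithm
#'
#' Draws `k` distinct row indices uniformly without replacement, the
#' initialization step of the traced k-means run. Holding these indices fixed
#' is part of the conditioning event of the selective test.
#'
#' @param x Numeric matrix or data frame, rows = observations.
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Optional integer seed; the draw is reproducible given the seed
#'   and leaves the caller's RNG state untouched.
#' @return Integer vector of `k` distinct row indices (1-based).
#' @export
sample_init_centroids <- function(x, k, seed = NULL) {
  x <- as_data_matrix(x)
  n <- nrow(x)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer", call. = FALSE)
  if (k > n) stop("`k` (", k, ") cannot exceed the number of rows (", n, ")",
                  call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  sample.int(n, k)
}

#' Assign observations to nearest centroids
#'
#' Squared-Euclidean nearest-centroid rule; ties are broken toward the lowest
#' cluster index. The identical rule is used wherever assignments are
#' (re-)evaluated, which is what makes the analytic conditioning set and the
#' brute-force re-clustering oracle comparable.
#'
#' @param x Numeric matrix (n x q).
#' @param centroids Numeric matrix (k x q).
#' @return Integer vector of n labels in `1..k`.
#' @export
assign_nearest <- function(x, centroids) {
  x <- rbind(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("all entries of `x` must be finite",
                               call. = FALSE)
  centroids <- rbind(centroids)
  if (ncol(centroids) != ncol(x))
    stop("`centroids` must have the same number of columns as `x`",
         call. = FALSE)
  assign_fast(x, centroids)
}

# ||x_i - c_k||^2 = ||x_i||^2 - 2 <x_i, c_k> + ||c_k||^2; the ||x_i||^2
# term is constant in k and dropped. max.col(ties="first") gives the
# lowest-index tie-break. No input validation: hot path.
assign_fast <- function(x, centroids) {
  scores <- 2 * tcrossprod(x, centroids) -
    matrix(rowSums(centroids^2), nrow(x), nrow(centroids), byrow = TRUE)
  max.col(scores, ties.method = "first")
}

#' Recompute centroids as within-cluster means
#'
#' @param x Numeric matrix (n x q).
#' @param labels Integer vector of n labels in `1..k`.
#' @param k Number of clusters.
#' @return Numeric matrix (k x q) of cluster means.
#' @export
update_centroids <- function(x, labels, k) {
  x <- as_data_matrix(x)
  stopifnot(length(labels) == nrow(x))
  counts <- tabulate(labels, nbins = k)
  if (any(counts == 0L))
    stop("empty cluster (label ", paste(which(counts == 0L), collapse = ", "),
         "): within-cluster mean weights are undefined",
         call. = FALSE)
  W <- cluster_weights(labels, k)
  W %*% x
}

# k x n row-stochastic matrix: row k holds 1/|C_k| on members of cluster k
cluster_weights <- function(labels, k) {
  n <- length(labels)
  counts <- tabulate(labels, nbins = k)
  W <- matrix(0, k, n)
  W[cbind(labels, seq_len(n))] <- 1 / counts[labels]
  W
}

#' Traced Lloyd's algorithm for k-means
#'
#' Runs Lloyd's algorithm from fixed initial centroid rows and retains every
#' intermediate assignment vector and centroid matrix. The complete trace
#' defines the conditioning event of the selective test: the event that
#' re-running the algorithm on perturbed data reproduces every intermediate
#' assignment.
#'
#' Iteration `t = 0` is the nearest-initial-centroid assignment; each later
#' iteration recomputes centroids from the previous assignment and reassigns.
#' The run stops when the assignment vector repeats (converged) or after
#' `max_iter` updates.
#'
#' @param x Numeric matrix or data frame (n x q).
#' @param k Number of clusters.
#' @param init Integer vector of `k` distinct row indices used as initial
#'   centroids, or `NULL` to sample them (see [sample_init_centroids()]).
#' @param seed Optional seed for the initial sampling (ignored when `init`
#'   is supplied).
#' @param max_iter Cap on the number of centroid updates (default 300). A
#'   trace that has not stabilized by then is still a valid conditioning
#'   event; it is flagged `converged = FALSE`.
#' @return An object of class `kmeans_trace`: a list with elements `k`,
#'   `init` (initial row indices), `assignments` ((T+1) x n integer matrix,
#'   row t+1 holding iteration-t labels), `centroids` (list of k x q
#'   matrices, element t+1 holding iteration-t centroids), `iter` (T, the
#'   number of updates), and `converged`.
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' tr <- kmeans_lloyd(x, k = 2, seed = 1)
#' tr$converged
#' table(final_labels(tr))
#' @export
kmeans_lloyd <- function(x, k, init = NULL, seed = NULL, max_iter = 300L) {
  x <- as_data_matrix(x)
  n <- nrow(x)
  if (is.null(init)) init <- sample_init_centroids(x, k, seed = seed)
  init <- as.integer(init)
  if (length(init) != k || anyDuplicated(init) ||
      any(init < 1L) || any(init > n))
    stop("`init` must be ", k, " distinct row indices in 1..", n,
         call. = FALSE)
  stopifnot(max_iter >= 1L)

  cent <- x[init, , drop = FALSE]
  labels <- assign_fast(x, cent)
  assignments <- matrix(labels, nrow = 1L)
  centroids <- list(cent)
  converged <- FALSE
  for (t in seq_len(max_iter)) {
    counts <- tabulate(labels, nbins = k)
    if (any(counts == 0L))
      stop("empty cluster at iteration ", t, " (label ",
           paste(which(counts == 0L), collapse = ", "),
           "); re-run with a different seed", call. = FALSE)
    cent <- cluster_weights(labels, k) %*% x
    new_labels <- assign_fast(x, cent)
    assignments <- rbind(assignments, new_labels)
    centroids[[t + 1L]] <- cent
    if (identical(new_labels, labels)) {
      converged <- TRUE
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  dimnames(assignments) <- NULL
  structure(
    list(k = as.integer(k), init = init, assignments = assignments,
         centroids = centroids, iter = nrow(assignments) - 1L,
         converged = converged),
    class = "kmeans_trace")
}

#' @export
print.kmeans_trace <- function(x, ...) {
  cat("<kmeans_trace> k =", x$k, "| n =", ncol(x$assignments),
      "| iterations =", x$iter,
      if (x$converged) "(converged)" else "(not converged)", "\n")
  cat("cluster sizes:", paste(tabulate(final_labels(x), x$k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Final cluster labels of a traced run
#'
#' @param trace A [kmeans_lloyd()] trace.
#' @return Integer vector of final labels in `1..k`.
#' @export
final_labels <- function(trace) {
  stopifnot(inherits(trace, "kmeans_trace"))
  trace$assignments[nrow(trace$assignments), ]
}

#' Within-cluster sum of squares of a labelling
#'
#' The k-means objective evaluated at a given assignment (cluster means
#' recomputed from the labels).
#'
#' @param x Numeric matrix.
#' @param labels Integer labels in `1..k`.
#' @param k Number of clusters.
#' @return Non-negative scalar.
#' @export
within_ss <- function(x, labels, k) {
  x <- as_data_matrix(x)
  cent <- update_centroids(x, labels, k)
  sum((x - cent[labels, , drop = FALSE])^2)
}
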