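#' Contrast vector for a pair of clusters
#'
#' Builds the observation-weight vector nu encoding the difference between
#' the empirical means of two clusters: entries are `1/n1` on cluster `k1`,
#' `-1/n2` on cluster `k2`, and zero elsewhere, so that `t(x) %*% nu` is the
#' difference between the two cluster centroids.
#'
#' @param labels Integer vector of cluster labels in `1..k`.
#' @param k1,k2 The two (distinct) cluster labels under test.
#' @return A list of class `contrast_vector`: `nu` (length-n vector),
#'   `pair = c(k1, k2)`, cardinalities `n1`, `n2`, and `nu_norm2 =
#'   1/n1 + 1/n2` (the squared Euclidean norm of `nu`).
#' @examples
#' contrast_vector(c(1, 1, 2, 2, 3), 1, 2)$nu
#' @export
contrast_vector <- function(labels, k1, k2) {
  if (k1 == k2) stop("`k1` and `k2` must differ", call. = FALSE)
  n1 <- sum(labels == k1)
  n2 <- sum(labels == k2)
  if (n1 == 0L || n2 == 0L)
    stop("both clusters must be non-empty in `labels` (sizes ", n1, ", ", n2,
         ")", call. = FALSE)
  nu <- numeric(length(labels))
  nu[labels == k1] <- 1 / n1
  nu[labels == k2] <- -1 / n2
  structure(list(nu = nu, pair = c(k1, k2), n1 = n1, n2 = n2,
                 nu_norm2 = 1 / n1 + 1 / n2),
            class = "contrast_vector")
}

#' Perturbation line through the observed data
#'
#' The selective test examines data perturbed along the cluster-mean
#' difference: row i of the perturbed matrix is
#' `base_i + phi * row_scales_i * direction`, affine in the scalar
#' perturbation coordinate `phi`. At `phi = phi_obs` (the observed statistic)
#' the original data are recovered exactly. In the spherical model
#' `direction` is the unit vector along `t(x) %*% nu`; in the known-covariance
#' extension it is a (generally non-unit) transformed direction, and the same
#' affine machinery applies.
#'
#' @param x Numeric data matrix (n x q).
#' @param contrast A [contrast_vector()].
#' @param direction Length-q vector, or `NULL` for the spherical default
#'   `dir(t(x) %*% nu)`.
#' @param phi_obs Observed coordinate at which the line passes through `x`;
#'   `NULL` for the spherical default `||t(x) %*% nu||`.
#' @return List of class `perturbation_line` with `base` (n x q),
#'   `row_scales` (`nu / ||nu||^2`), `direction`, and `phi_obs`.
#' @export
perturbation_line <- function(x, contrast, direction = NULL, phi_obs = NULL) {
  x <- as_data_matrix(x)
  stopifnot(inherits(contrast, "contrast_vector"))
  xtnu <- drop(crossprod(x, contrast$nu))
  stat <- sqrt(sum(xtnu^2))
  if (is.null(direction)) {
    direction <- if (stat > 0) xtnu / stat else numeric(ncol(x))
  }
  if (is.null(phi_obs)) phi_obs <- stat
  if (all(direction == 0) && phi_obs > 0 && stat > 0)
    stop("zero perturbation direction with a nonzero observed statistic",
         call. = FALSE)
  s <- contrast$nu / contrast$nu_norm2
  base <- x - phi_obs * outer(s, direction)
  structure(list(base = base, row_scales = s, direction = direction,
                 phi_obs = phi_obs),
            class = "perturbation_line")
}

#' Evaluate a perturbation line at a coordinate
#'
#' @param line A [perturbation_line()].
#' @param phi Scalar perturbation coordinate.
#' @return The n x q perturbed data matrix.
#' @export
perturbed_data <- function(line, phi) {
  stopifnot(inherits(line, "perturbation_line"))
  line$base + phi * outer(line$row_scales, line$direction)
}

# Quadratic coefficients (a, b, c) of || u + phi v ||^2 where
# u = rowdiff of base, v = scalediff * direction: a = scalediff^2 ||d||^2,
# b = 2 scalediff <u, d>, c = ||u||^2. Shared by the pairwise (Lemma-3-type)
# and weighted-centroid (Lemma-4-type) cases.
affine_sq_norm_coeffs <- function(u, scalediff, direction) {
  dn2 <- sum(direction^2)
  c(a = scalediff^2 * dn2,
    b = 2 * scalediff * sum(u * direction),
    c = sum(u^2))
}

#' Quadratic coefficients of a pairwise squared distance
#'
#' The squared distance between rows i and j of the perturbed data is an
#' exact quadratic in phi; this returns its coefficients `(a, b, c)` with
#' `a phi^2 + b phi + c = || x'(phi)_i - x'(phi)_j ||^2`.
#'
#' @param line A [perturbation_line()].
#' @param i,j Distinct row indices.
#' @return Named numeric vector `(a, b, c)`.
#' @export
pairwise_coeffs <- function(line, i, j) {
  stopifnot(inherits(line, "perturbation_line"), i != j)
  u <- line$base[i, ] - line$base[j, ]
  affine_sq_norm_coeffs(u, line$row_scales[i] - line$row_scales[j],
                        line$direction)
}

#' Quadratic coefficients of a distance to a weighted centroid
#'
#' The squared distance from row i of the perturbed data to a fixed convex
#' combination of its rows (a within-cluster mean under the original
#' labelling) is an exact quadratic in phi.
#'
#' @param line A [perturbation_line()].
#' @param i Row index.
#' @param weights Length-n non-negative weights summing to 1.
#' @param tol Tolerance on the weight-sum check.
#' @return Named numeric vector `(a, b, c)`.
#' @export
weighted_coeffs <- function(line, i, weights, tol = 1e-8) {
  stopifnot(inherits(line, "perturbation_line"))
  if (abs(sum(weights) - 1) > tol || any(weights < 0))
    stop("`weights` must be non-negative and sum to 1", call. = FALSE)
  u <- line$base[i, ] - drop(crossprod(line$base, weights))
  affine_sq_norm_coeffs(u, line$row_scales[i] - sum(weights * line$row_scales),
                        line$direction)
}

#' Quadratic constraints characterizing the conditioning event
#'
#' The event that re-running the traced Lloyd's algorithm on perturbed data
#' reproduces every intermediate assignment decomposes into n*k*(T+1)
#' "assigned centroid at least as close as competitor centroid" conditions.
#' Each is the difference of two exact quadratics in phi, hence quadratic:
#' `a phi^2 + b phi + c <= 0`. At iteration 0 the centroids are the (held
#' fixed) initial rows of the perturbed data; at iteration t >= 1 they are
#' weighted means with weights frozen from the original trace's iteration
#' t-1 labels. Rows with `k == assigned` are identically zero.
#'
#' @param line A [perturbation_line()] built on the data of `trace`.
#' @param trace A [kmeans_lloyd()] trace on the same data.
#' @return A tibble with columns `t` (iteration, 0-based), `i` (observation),
#'   `k` (competitor cluster), and coefficients `a`, `b`, `c`.
#' @export
build_constraints <- function(line, trace) {
  stopifnot(inherits(line, "perturbation_line"),
            inherits(trace, "kmeans_trace"))
  mats <- constraint_coeff_mats(line, trace)
  out <- dplyr::bind_rows(lapply(seq_along(mats), function(ti) {
    m <- mats[[ti]]
    tibble::tibble(t = ti - 1L, i = m$i, k = m$k,
                   a = m$a, b = m$b, c = m$c)
  }))
  out
}

# Vectorized coefficient computation. For iteration t the constraint for
# (i, competitor k) is quad(i, assigned_i) - quad(i, k) where quad(i, k) is
# the squared distance from perturbed row i to perturbed centroid k:
#   a_ik = (s_i - cs_k)^2 ||d||^2
#   b_ik = 2 (s_i - cs_k) (<B_i, d> - <C_k, d>)
#   c_ik = ||B_i||^2 - 2 <B_i, C_k> + ||C_k||^2
# with B the base matrix, s the row scales, and (C, cs) the centroid rows of
# (B, s): initial rows at t = 0, frozen-weight means at t >= 1.
# Returns, per iteration, all n*k (i, k) rows including the zero self rows.
constraint_coeff_mats <- function(line, trace) {
  B <- line$base
  s <- line$row_scales
  d <- line$direction
  n <- nrow(B)
  k <- trace$k
  dn2 <- sum(d^2)
  Bd <- drop(B %*% d)
  Bn2 <- rowSums(B^2)
  lapply(seq_len(trace$iter + 1L), function(ti) {
    t0 <- ti - 1L
    if (t0 == 0L) {
      C <- B[trace$init, , drop = FALSE]
      cs <- s[trace$init]
    } else {
      W <- cluster_weights(trace$assignments[t0, ], k)
      C <- W %*% B
      cs <- drop(W %*% s)
    }
    Cd <- drop(C %*% d)
    Cn2 <- rowSums(C^2)
    G <- outer(s, cs, "-")                       # n x k: s_i - cs_k
    A <- G^2 * dn2
    Bc <- 2 * G * outer(Bd, Cd, "-")
    Cc <- Bn2 - 2 * tcrossprod(B, C) + matrix(Cn2, n, k, byrow = TRUE)
    assigned <- trace$assignments[ti, ]          # labels c^(t)
    idx <- cbind(seq_len(n), assigned)
    list(i = rep(seq_len(n), k), k = rep(seq_len(k), each = n),
         a = as.vector(A[idx] - A), b = as.vector(Bc[idx] - Bc),
         c = as.vector(Cc[idx] - Cc))
  })
}

#' Truncation set of the selective test
#'
#' Intersects the solution sets of all conditioning constraints, then with
#' the non-negative half-line (the support of the scaled chi reference
#' distribution). The observed coordinate `phi_obs` always belongs to the
#' result, up to floating-point tolerance at interval endpoints.
#'
#' @param line A [perturbation_line()].
#' @param trace The [kmeans_lloyd()] trace on the same data.
#' @param tol Degeneracy/endpoint tolerance passed to the quadratic solver.
#' @return An [interval_union()] subset of `[0, Inf)`.
#' @export
truncation_region <- function(line, trace, tol = 1e-10) {
  mats <- constraint_coeff_mats(line, trace)
  a <- unlist(lapply(mats, `[[`, "a"), use.names = FALSE)
  b <- unlist(lapply(mats, `[[`, "b"), use.names = FALSE)
  cc <- unlist(lapply(mats, `[[`, "c"), use.names = FALSE)
  keep <- abs(a) + abs(b) + abs(cc) > 0      # drop identically-zero self rows
  sol <- solve_quads_vec(a[keep], b[keep], cc[keep], tol = tol)
  if (sol$any_empty) return(iu_empty())
  sweep_intersect(c(sol$lo, 0), c(sol$hi, Inf), m = sol$n_sets + 1L)
}

# Vectorized solver for many a*phi^2 + b*phi + c <= 0 constraints at once.
# Each constraint whose solution set is not the whole line contributes one
# "set" made of one or two intervals; returns flat lo/hi vectors and the
# number of contributing sets. Mirrors solve_quadratic_inequality's case
# analysis, including the near-zero-discriminant guards.
solve_quads_vec <- function(a, b, cc, tol) {
  m <- pmax(abs(a), abs(b), abs(cc))
  zero <- m < tol
  az <- !zero & abs(a) <= tol * m
  const <- az & abs(b) <= tol * m
  lin <- az & !const
  quad <- !zero & !az
  any_empty <- any(const & cc > 0)

  lo <- numeric(0); hi <- numeric(0); n_sets <- 0L
  if (any(lin)) {
    r <- -cc[lin] / b[lin]
    pos <- b[lin] > 0
    lo <- c(lo, ifelse(pos, -Inf, r))
    hi <- c(hi, ifelse(pos, r, Inf))
    n_sets <- n_sets + sum(lin)
  }
  if (any(quad)) {
    aq <- a[quad]; bq <- b[quad]; cq <- cc[quad]
    disc <- bq * bq - 4 * aq * cq
    dtol <- tol * pmax(bq * bq, abs(4 * aq * cq), 1)
    dbl <- abs(disc) < dtol                     # vertex grazing zero
    s <- sqrt(pmax(disc, 0))
    qq <- -(bq + sign(bq + (bq == 0)) * s) / 2
    r1 <- qq / aq
    r2 <- ifelse(qq != 0, cq / qq, -bq / (2 * aq))
    rlo <- pmin(r1, r2); rhi <- pmax(r1, r2)
    rv <- -bq / (2 * aq)                        # vertex

    posa <- aq > 0
    # a > 0: [rlo, rhi]; empty if disc truly negative; [rv, rv] if grazing
    sel <- posa & disc >= dtol
    lo <- c(lo, rlo[sel]); hi <- c(hi, rhi[sel])
    selg <- posa & dbl
    lo <- c(lo, rv[selg]); hi <- c(hi, rv[selg])
    any_empty <- any_empty || any(posa & disc <= -dtol)
    n_sets <- n_sets + sum(sel) + sum(selg)
    # a < 0: complement of (rlo, rhi) if disc truly positive, else all reals
    seln <- !posa & disc >= dtol
    if (any(seln)) {
      lo <- c(lo, rep(-Inf, sum(seln)), rhi[seln])
      hi <- c(hi, rlo[seln], rep(Inf, sum(seln)))
      n_sets <- n_sets + sum(seln)
    }
  }
  list(lo = lo, hi = hi, n_sets = n_sets, any_empty = any_empty)
}

# Endpoint-sort sweep intersection of m interval sets given as flat lo/hi
# vectors (intervals within a set disjoint; two-interval sets contribute two
# rows). A point is in the intersection where all m sets are open.
sweep_intersect <- function(lo, hi, m) {
  pos <- c(lo, hi)
  typ <- rep(c(1L, -1L), c(length(lo), length(hi)))
  ord <- order(pos, -typ)
  pos <- pos[ord]
  depth <- cumsum(typ[ord])
  starts <- which(depth == m)
  if (length(starts) == 0L) return(iu_empty())
  interval_union(pos[starts], pos[starts + 1L])
}
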