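#' Finite unions of disjoint real intervals
#'
#' An `interval_union` is the package's representation of subsets of the real
#' line arising as solution sets of quadratic inequalities and their
#' intersections, in particular the truncation set of the selective test.
#' Intervals are stored closed (endpoints included); the reference
#' distribution is continuous, so boundary conventions carry no probability
#' mass. Endpoints may be `-Inf` / `Inf`.
#'
#' @param lo,hi Numeric vectors of equal length: lower and upper endpoints.
#'   Intervals with `lo > hi` are dropped; overlapping or touching intervals
#'   are merged so the result is canonical (sorted, pairwise disjoint).
#'
#' @return An object of class `interval_union`: a two-column numeric matrix
#'   with columns `lo` and `hi`, zero rows for the empty set.
#' @examples
#' interval_union(c(0, 3), c(5, 9))   # merges to [0, 9]
#' interval_union(numeric(0), numeric(0))  # empty set
#' @export
interval_union <- function(lo = numeric(0), hi = numeric(0)) {
  stopifnot(length(lo) == length(hi))
  keep <- !is.na(lo) & !is.na(hi) & lo <= hi
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) > 1L) {
    ord <- order(lo, hi)
    lo <- lo[ord]; hi <- hi[ord]
    # single left-to-right merge pass; touching closed intervals coalesce
    out_lo <- lo[1L]; out_hi <- hi[1L]
    m <- 1L
    for (j in seq_along(lo)[-1L]) {
      if (lo[j] <= out_hi[m]) {
        if (hi[j] > out_hi[m]) out_hi[m] <- hi[j]
      } else {
        m <- m + 1L
        out_lo[m] <- lo[j]; out_hi[m] <- hi[j]
      }
    }
    lo <- out_lo; hi <- out_hi
  }
  structure(cbind(lo = lo, hi = hi), class = "interval_union")
}

#' @export
print.interval_union <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<interval_union: empty set>\n")
  } else {
    cat("<interval_union>",
        paste0("[", format(x[, "lo"]), ", ", format(x[, "hi"]), "]",
               collapse = " U "), "\n")
  }
  invisible(x)
}

iu_empty <- function() interval_union()
iu_reals <- function() interval_union(-Inf, Inf)

#' @rdname interval_union
#' @param x Object to test or convert.
#' @export
is_interval_union <- function(x) inherits(x, "interval_union")

#' Convert an interval union to a tibble
#'
#' @param x An [interval_union()].
#' @param ... Unused.
#' @return A tibble with columns `lo` and `hi`, one row per interval.
#' @method tidy interval_union
#' @export
tidy.interval_union <- function(x, ...) {
  tibble::tibble(lo = as.numeric(x[, "lo"]), hi = as.numeric(x[, "hi"]))
}

#' Membership in an interval union
#'
#' @param phi Numeric vector of points.
#' @param region An [interval_union()].
#' @param tol Slack applied at endpoints, on the scale of `phi`.
#' @return Logical vector: is each point inside the union?
#' @export
iu_contains <- function(phi, region, tol = 0) {
  stopifnot(is_interval_union(region))
  if (nrow(region) == 0L) return(rep(FALSE, length(phi)))
  vapply(phi, function(p)
    any(region[, "lo"] - tol <= p & p <= region[, "hi"] + tol), logical(1))
}

#' Solve a quadratic inequality a*phi^2 + b*phi + c <= 0
#'
#' Exact case analysis over the reals, with a tolerance guarding the
#' degenerate (linear, constant, double-root) cases. Coefficients whose
#' largest magnitude falls below `tol` are treated as the zero polynomial,
#' whose solution set is the whole line.
#'
#' @param a,b,c Finite numeric coefficients.
#' @param tol Degeneracy tolerance (default `1e-10`); compared against the
#'   coefficients on their own scale.
#' @return An [interval_union()] (possibly empty or all of the reals).
#' @examples
#' solve_quadratic_inequality(1, 0, -4)    # [-2, 2]
#' solve_quadratic_inequality(-1, 0, 1)    # (-Inf, -1] U [1, Inf)
#' solve_quadratic_inequality(0, 2, -2)    # (-Inf, 1]
#' @export
solve_quadratic_inequality <- function(a, b, c, tol = 1e-10) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  m <- max(abs(a), abs(b), abs(c))
  if (m < tol) return(iu_reals())            # zero polynomial
  if (abs(a) <= tol * m) {
    if (abs(b) <= tol * m) {                  # constant polynomial
      return(if (c <= 0) iu_reals() else iu_empty())
    }
    r <- -c / b                               # linear case
    return(if (b > 0) interval_union(-Inf, r) else interval_union(r, Inf))
  }
  disc <- b * b - 4 * a * c
  dtol <- tol * max(b * b, abs(4 * a * c), 1)
  if (abs(disc) < dtol) {
    # vertex grazing zero: a double root for convex, no exclusion for concave
    r <- -b / (2 * a)
    return(if (a > 0) interval_union(r, r) else iu_reals())
  }
  if (disc < 0) return(if (a > 0) iu_empty() else iu_reals())
  # numerically stable roots
  s <- sqrt(disc)
  qq <- -(b + sign(b + (b == 0)) * s) / 2
  r1 <- qq / a
  r2 <- if (qq != 0) c / qq else -b / (2 * a)
  lo <- min(r1, r2); hi <- max(r1, r2)
  if (a > 0) interval_union(lo, hi)
  else interval_union(c(-Inf, hi), c(lo, Inf))
}

#' Intersect a list of interval unions
#'
#' Implemented as a single sweep over all interval endpoints: every interval
#' contributes an opening and a closing event; a point belongs to the
#' intersection exactly where all sets are open simultaneously. Sorting the
#' O(m) endpoints dominates the cost.
#'
#' @param sets A list of [interval_union()] objects. The empty list yields
#'   the whole real line (empty-intersection convention).
#' @return The canonical [interval_union()] intersection.
#' @examples
#' intersect_all(list(interval_union(0, 5), interval_union(3, 9)))  # [3, 5]
#' @export
intersect_all <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) == 0L) return(iu_reals())
  nivl <- vapply(sets, nrow, integer(1))
  if (any(nivl == 0L)) return(iu_empty())
  m <- length(sets)
  lo <- unlist(lapply(sets, function(s) s[, "lo"]), use.names = FALSE)
  hi <- unlist(lapply(sets, function(s) s[, "hi"]), use.names = FALSE)
  # events: +1 at lo, -1 at hi; at equal coordinates openings sort first so
  # that touching closed intervals still meet (possibly in a single point)
  pos <- c(lo, hi)
  typ <- rep(c(1L, -1L), c(length(lo), length(hi)))
  ord <- order(pos, -typ)
  pos <- pos[ord]; typ <- typ[ord]
  depth <- cumsum(typ)
  starts <- which(depth == m)
  if (length(starts) == 0L) return(iu_empty())
  out_lo <- pos[starts]
  out_hi <- pos[starts + 1L]   # next event after full depth is a closing
  interval_union(out_lo, out_hi)
}
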