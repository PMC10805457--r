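#' Brute-force truncation-set membership by re-clustering
#'
#' The independent check of the analytic truncation region: for each
#' candidate perturbation coordinate, build the perturbed data, re-run the
#' traced Lloyd's algorithm from the *same* initial centroid rows with the
#' *same* tie-break for exactly as many updates as the original run, and
#' report whether every intermediate assignment is reproduced. Agreement
#' with [truncation_region()] away from interval endpoints is the central
#' correctness property of the package.
#'
#' @param line A [perturbation_line()].
#' @param trace The [kmeans_lloyd()] trace the line was built on.
#' @param grid Numeric vector of perturbation coordinates to probe.
#' @return Logical vector, one entry per grid point.
#' @export
grid_oracle_region <- function(line, trace, grid) {
  stopifnot(inherits(line, "perturbation_line"),
            inherits(trace, "kmeans_trace"))
  vapply(grid, function(phi) replay_matches(perturbed_data(line, phi), trace),
         logical(1))
}

# Re-run assignment/update steps on xp for exactly trace$iter updates,
# stopping early on the first mismatch. Uses the same nearest-centroid
# tie-break as the original run. Centroids are recomputed from the replay's
# own labels; since we bail on the first mismatch these always coincide
# with the original labelling when reached.
replay_matches <- function(xp, trace) {
  labels <- assign_fast(xp, xp[trace$init, , drop = FALSE])
  if (!identical(labels, trace$assignments[1L, ])) return(FALSE)
  k <- trace$k
  for (t in seq_len(trace$iter)) {
    if (any(tabulate(labels, nbins = k) == 0L)) return(FALSE)
    cent <- cluster_weights(labels, k) %*% xp
    labels <- assign_fast(xp, cent)
    if (!identical(labels, trace$assignments[t + 1L, ])) return(FALSE)
  }
  TRUE
}

#' Monte Carlo (rejection sampling) selective p-value
#'
#' Independent estimate of the selective p-value: draw the perturbation
#' coordinate from its scaled chi reference distribution, keep the draws
#' whose re-clustering reproduces the original trace (checked by brute
#' force, not via the analytic region), and report the fraction of accepted
#' draws at or above the observed statistic. Used to validate
#' [truncated_chi_survival()] on the analytic region.
#'
#' @param line A [perturbation_line()].
#' @param trace The matching [kmeans_lloyd()] trace.
#' @param df Degrees of freedom of the chi reference (number of features).
#' @param scale Scale of the chi reference (`sigma * ||nu||`).
#' @param draws Number of Monte Carlo draws.
#' @param seed Optional integer seed (local to this call).
#' @return A list with `estimate`, `se` (binomial standard error),
#'   `n_accepted` and `draws`.
#' @export
mc_oracle_p <- function(line, trace, df, scale, draws = 1e5, seed = NULL) {
  stopifnot(scale > 0, draws >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  phi <- scale * sqrt(rchisq(draws, df = df))
  acc <- grid_oracle_region(line, trace, phi)
  n_acc <- sum(acc)
  if (n_acc == 0L)
    stop("no accepted draws; increase `draws` (the conditioning event is ",
         "rare under the reference distribution)", call. = FALSE)
  est <- mean(phi[acc] >= line$phi_obs)
  list(estimate = est, se = sqrt(est * (1 - est) / n_acc),
       n_accepted = n_acc, draws = draws)
}
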