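#' Naive chi-distribution p-value
#'
#' Survival probability of the observed statistic under a scaled chi
#' reference distribution with `df` degrees of freedom: the Wald-type
#' p-value that ignores how the tested clusters were chosen. After
#' clustering it is severely anti-conservative; it is reported alongside the
#' selective p-value for comparison.
#'
#' @param stat Non-negative observed statistic.
#' @param df Degrees of freedom (the number of features q).
#' @param scale Positive scale (`sigma * ||nu||` in the spherical model).
#' @return A p-value in `[0, 1]`.
#' @export
naive_p <- function(stat, df, scale) {
  stopifnot(stat >= 0, df >= 1, scale > 0)
  pchisq((stat / scale)^2, df = df, lower.tail = FALSE)
}

# log(exp(x) - exp(y)) for x >= y, stable for close arguments
logspace_sub <- function(x, y) {
  if (y == -Inf) return(x)
  if (x <= y) return(-Inf)
  x + log1p(-exp(y - x))
}

logsumexp <- function(v) {
  v <- v[v > -Inf]
  if (length(v) == 0L) return(-Inf)
  mx <- max(v)
  mx + log(sum(exp(v - mx)))
}

# log P(chisq_df in [a2, b2]) via survival differences, with a midpoint
# density x width fallback when cancellation in the difference of survival
# functions underflows (narrow intervals deep in either tail).
log_chisq_interval_mass <- function(a2, b2, df) {
  ls_a <- pchisq(a2, df = df, lower.tail = FALSE, log.p = TRUE)
  ls_b <- if (is.infinite(b2)) -Inf else
    pchisq(b2, df = df, lower.tail = FALSE, log.p = TRUE)
  out <- logspace_sub(ls_a, ls_b)
  if (out == -Inf && is.finite(b2) && b2 > a2) {
    out <- dchisq((a2 + b2) / 2, df = df, log = TRUE) + log(b2 - a2)
  }
  out
}

#' Survival function of a truncated scaled chi distribution
#'
#' Computes `P(phi >= stat, phi in region) / P(phi in region)` for
#' `phi ~ scale * chi_df` restricted to a union of intervals: the selective
#' p-value once the truncation region is known. Interval masses are
#' accumulated in log space so that regions far in the tail (where both
#' numerator and denominator underflow in linear arithmetic) still return a
#' finite ratio.
#'
#' @param stat Non-negative observed statistic, a member of `region`.
#' @param df Degrees of freedom.
#' @param scale Positive scale.
#' @param region An [interval_union()] subset of `[0, Inf)`.
#' @return A p-value in `[0, 1]`.
#' @export
truncated_chi_survival <- function(stat, df, scale, region) {
  stopifnot(stat >= 0, df >= 1, scale > 0, is_interval_union(region))
  if (nrow(region) == 0L)
    stop("empty truncation region: no reference mass", call. = FALSE)
  lo <- pmax(region[, "lo"], 0)
  hi <- region[, "hi"]
  ok <- hi >= lo
  lo <- lo[ok]; hi <- hi[ok]
  if (length(lo) == 0L)
    stop("truncation region has no mass on [0, Inf)", call. = FALSE)
  a2 <- (lo / scale)^2
  b2 <- (hi / scale)^2
  log_den <- logsumexp(mapply(log_chisq_interval_mass, a2, b2,
                              MoreArgs = list(df = df)))
  # numerator: region clipped to [stat, Inf)
  nlo <- pmax(lo, stat)
  keep <- hi >= nlo
  if (!any(keep)) return(0)
  log_num <- logsumexp(mapply(log_chisq_interval_mass,
                              (nlo[keep] / scale)^2, b2[keep],
                              MoreArgs = list(df = df)))
  if (log_den == -Inf) {
    stop("truncation region mass underflowed even in log space; ",
         "use the Monte Carlo oracle (mc_oracle_p) for this case",
         call. = FALSE)
  }
  min(1, max(0, exp(log_num - log_den)))
}

#' Median-based noise level estimator
#'
#' Robust plug-in estimator of the noise standard deviation: centres each
#' column at its median, then matches the median of the squared residuals to
#' the median of the chi-squared(1) distribution. Consistent when the mean
#' matrix is sparse, and much less affected by true cluster structure than
#' the sample estimator.
#'
#' @param x Numeric matrix or data frame.
#' @return Non-negative scalar estimate; zero (with a warning) for a matrix
#'   with no within-column variation.
#' @export
sigma_med <- function(x) {
  x <- as_data_matrix(x)
  xt <- sweep(x, 2, apply(x, 2, median))
  med <- median(xt^2)
  if (med == 0) {
    warning("no within-column variation; sigma_med is 0")
    return(0)
  }
  sqrt(med / qchisq(0.5, df = 1))
}

#' Column-centred sample noise level estimator
#'
#' Root mean square of column-mean-centred entries with divisor `n*q - q`.
#' Upward-biased in the presence of true cluster mean structure, making the
#' resulting plug-in test conservative.
#'
#' @param x Numeric matrix or data frame with at least two rows.
#' @return Non-negative scalar estimate.
#' @export
sigma_sample <- function(x) {
  x <- as_data_matrix(x)
  n <- nrow(x); q <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  sqrt(sum(xc^2) / (n * q - q))
}

#' Symmetric inverse square root of a positive-definite matrix
#'
#' @param Sigma Symmetric positive-definite q x q matrix.
#' @param tol Relative eigenvalue tolerance for the positive-definiteness
#'   check.
#' @return The unique symmetric positive-definite `M` with
#'   `M %*% Sigma %*% M = I`.
#' @export
inv_sqrt_psd <- function(Sigma, tol = 1e-10) {
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != ncol(Sigma) || max(abs(Sigma - t(Sigma))) >
      tol * max(1, max(abs(Sigma))))
    stop("`Sigma` must be a symmetric square matrix", call. = FALSE)
  Sigma <- (Sigma + t(Sigma)) / 2
  e <- eigen(Sigma, symmetric = TRUE)
  if (any(e$values <= tol * max(e$values)))
    stop("`Sigma` is not positive definite", call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# symmetric PSD square root (used by the direct-covariance perturbation)
sqrt_psd <- function(Sigma) {
  Sigma <- (Sigma + t(Sigma)) / 2
  e <- eigen(Sigma, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' Ridge-regularized whitening transform from the sample covariance
#'
#' Eigendecomposes the sample covariance `U Lambda U'` of `x` and returns
#' `U (Lambda + ridge I)^{-1/2} U'`, the regularized inverse square root
#' used to de-correlate features before clustering when no covariance is
#' known. The ridge keeps the transform well defined when the sample
#' covariance is rank deficient (e.g. q > n).
#'
#' @param x Numeric matrix or data frame with at least two rows.
#' @param ridge Non-negative regularization added to every eigenvalue
#'   (default 0.01).
#' @return Symmetric positive-definite q x q matrix.
#' @export
ridge_whitening_estimate <- function(x, ridge = 0.01) {
  x <- as_data_matrix(x)
  stopifnot(ridge >= 0)
  S <- cov(x)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0) + ridge
  if (any(vals <= 0))
    stop("sample covariance is singular; use a positive `ridge`",
         call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}
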