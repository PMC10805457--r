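test_that("naive p-value is the scaled chi survival function", {
  expect_equal(naive_p(0, 3, 1), 1)
  stats <- seq(0, 5, 0.5)
  ps <- vapply(stats, naive_p, numeric(1), df = 4, scale = 2)
  expect_true(all(diff(ps) <= 0))
  # scale times the chi median maps to p = 0.5 (quantile-function oracle)
  for (df in c(1, 2, 10)) {
    med <- sqrt(qchisq(0.5, df))
    expect_equal(naive_p(1.7 * med, df, 1.7), 0.5, tolerance = 1e-12)
  }
})

test_that("truncated chi survival handles canonical regions", {
  full <- interval_union(0, Inf)
  expect_equal(truncated_chi_survival(2.2, df = 3, scale = 1.3, region = full),
               naive_p(2.2, 3, 1.3), tolerance = 1e-12)
  expect_equal(truncated_chi_survival(2, 3, 1, interval_union(2, Inf)), 1)
  expect_equal(truncated_chi_survival(2, 3, 1, interval_union(0, 2)), 0)
  # multi-interval region: direct linear-space ratio on a moderate case
  reg <- interval_union(c(0.5, 2.5), c(1.5, 4))
  num <- (pchisq(4^2, 2, lower.tail = FALSE) -
            pchisq(3^2, 2, lower.tail = FALSE)) * -1
  num <- pchisq(3^2, 2, lower.tail = FALSE) - pchisq(4^2, 2, lower.tail = FALSE)
  den <- (pchisq(0.5^2, 2, lower.tail = FALSE) -
            pchisq(1.5^2, 2, lower.tail = FALSE)) + num +
    (pchisq(2.5^2, 2, lower.tail = FALSE) - pchisq(3^2, 2, lower.tail = FALSE))
  expect_equal(truncated_chi_survival(3, 2, 1, reg), num / den,
               tolerance = 1e-10)
  expect_error(truncated_chi_survival(1, 2, 1, interval_union()), "empty")
})

test_that("deep-tail truncation regions return finite probabilities", {
  # both masses underflow in linear space; the log-space path must not
  p <- truncated_chi_survival(60, df = 2, scale = 1,
                              region = interval_union(59, Inf))
  expect_true(p > 0 && p < 1)
  # agree with the exponential tail ratio exp(-(s^2-l^2)/2) for chi_2
  expect_equal(p, exp(-(60^2 - 59^2) / 2), tolerance = 1e-6)
})

test_that("sigma_med matches its defining formula and degenerates cleanly", {
  expect_warning(s0 <- sigma_med(matrix(3, 5, 4)), "no within-column")
  expect_equal(s0, 0)
  x <- withr::with_seed(2, matrix(rnorm(60, 5, 1), 20, 3))
  xt <- sweep(x, 2, apply(x, 2, median))
  expect_equal(sigma_med(x), sqrt(median(xt^2) / qchisq(0.5, 1)))
  # consistency at large n*q
  big <- withr::with_seed(3, matrix(rnorm(1e5, 0, 2), 1000, 100))
  expect_lt(abs(sigma_med(big) - 2) / 2, 0.05)
})

test_that("sigma_sample is the column-centred RMS and is conservative under structure", {
  expect_equal(sigma_sample(matrix(7, 4, 3)), 0)
  expect_equal(sigma_sample(matrix(c(0, 2), 2, 1)), sqrt(2))
  # upward bias under true cluster separation: exceeds sigma_med on average
  diffs <- vapply(1:6, function(s) {
    g <- gen_three_cluster(60, 4, delta = 6, sigma = 1, seed = s)
    sigma_sample(g$x) - sigma_med(g$x)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("plug-in tests reuse the known-sigma region and respond to scale", {
  x <- gen_global_null(30, 3, 1, seed = 14)
  known <- kmeans_sel_test(x, 2, c(1, 2), sigma = 1, seed = 7)
  med <- kmeans_sel_test(x, 2, c(1, 2), sigma = "med", seed = 7)
  samp <- kmeans_sel_test(x, 2, c(1, 2), sigma = "sample", seed = 7)
  expect_identical(unclass(known$region), unclass(med$region))
  expect_identical(unclass(known$region), unclass(samp$region))
  expect_identical(med$sigma_source, "med")
  # survival at larger reference scale is larger, statistic and region fixed
  scales <- sort(c(known$sigma, med$sigma, samp$sigma, 0.5, 2))
  ps <- vapply(scales, function(s)
    truncated_chi_survival(known$stat, known$df,
                           s * sqrt(known$contrast$nu_norm2), known$region),
    numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("inverse symmetric square roots invert the covariance", {
  expect_equal(inv_sqrt_psd(diag(3)), diag(3))
  expect_equal(inv_sqrt_psd(diag(c(4, 9))), diag(c(1/2, 1/3)))
  S <- withr::with_seed(4, crossprod(matrix(rnorm(25), 5, 5)) + diag(5))
  M <- inv_sqrt_psd(S)
  expect_equal(M, t(M), tolerance = 1e-10)
  expect_equal(M %*% S %*% M, diag(5), tolerance = 1e-8)
  expect_error(inv_sqrt_psd(matrix(c(1, 2, 2, 1), 2)), "not positive definite")
  expect_error(inv_sqrt_psd(matrix(1:6, 2, 3)), "symmetric")
})

test_that("whitening with the identity changes nothing", {
  x <- gen_global_null(24, 2, 1, seed = 21)
  a <- kmeans_sel_test(x, 2, c(1, 2), sigma = 1, seed = 5)
  b <- kmeans_sel_test_cov(x, diag(2), 2, c(1, 2), mode = "whiten", seed = 5)
  expect_equal(a$p_selective, b$p_selective, tolerance = 1e-10)
  expect_equal(a$stat, b$stat, tolerance = 1e-10)
  expect_identical(final_labels(a$trace), final_labels(b$trace))
})

test_that("direct covariance conditioning reduces to the spherical test for isotropic Sigma", {
  x <- gen_global_null(24, 3, 1, seed = 31)
  sph1 <- kmeans_sel_test(x, 2, c(1, 2), sigma = 1, seed = 9)
  cov1 <- kmeans_sel_test_cov(x, diag(3), 2, c(1, 2), mode = "direct",
                              seed = 9)
  expect_identical(final_labels(sph1$trace), final_labels(cov1$trace))
  expect_equal(cov1$stat, sph1$stat, tolerance = 1e-10)
  expect_equal(unclass(cov1$region), unclass(sph1$region), tolerance = 1e-8)
  expect_equal(cov1$p_selective, sph1$p_selective, tolerance = 1e-9)
  # Sigma = sigma^2 I: same trace, p equal, region on the whitened scale
  sig <- 2
  sph2 <- kmeans_sel_test(x, 2, c(1, 2), sigma = sig, seed = 9)
  cov2 <- kmeans_sel_test_cov(x, sig^2 * diag(3), 2, c(1, 2),
                              mode = "direct", seed = 9)
  expect_identical(final_labels(sph2$trace), final_labels(cov2$trace))
  expect_equal(cov2$stat, sph2$stat / sig, tolerance = 1e-10)
  expect_equal(unclass(cov2$region), unclass(sph2$region) / sig,
               tolerance = 1e-8)
  expect_equal(cov2$p_selective, sph2$p_selective, tolerance = 1e-9)
})

test_that("direct covariance regions agree with the re-clustering oracle", {
  ar1 <- function(q, rho) rho^abs(outer(1:q, 1:q, "-"))
  for (seed in c(2, 5)) {
    Sig <- ar1(3, 0.6)
    x <- withr::with_seed(seed,
      matrix(rnorm(16 * 3), 16, 3) %*% chol(Sig))
    res <- kmeans_sel_test_cov(x, Sig, 2, c(1, 2), mode = "direct",
                               seed = seed + 7)
    cv <- contrast_vector(final_labels(res$trace), 1, 2)
    M <- inv_sqrt_psd(Sig)
    xtnu <- drop(crossprod(x, cv$nu))
    wst <- drop(M %*% xtnu)
    dvec <- drop(selkmeans:::sqrt_psd(Sig) %*% (wst / sqrt(sum(wst^2))))
    line <- perturbation_line(x, cv, direction = dvec,
                              phi_obs = sqrt(sum(wst^2)))
    expect_true(iu_contains(res$stat, res$region, tol = 1e-8))
    grid <- seq(0, res$stat + 5 * sqrt(cv$nu_norm2), length.out = 150)
    ends <- as.numeric(res$region)
    off <- !vapply(grid, function(g) any(abs(g - ends) < 1e-6), logical(1))
    expect_identical(iu_contains(grid, res$region)[off],
                     grid_oracle_region(line, res$trace, grid)[off])
  }
})

test_that("ridge whitening matches its eigendecomposition definition", {
  x0 <- withr::with_seed(6, matrix(rnorm(200), 50, 4))
  xc <- sweep(x0, 2, colMeans(x0))
  xw <- xc %*% inv_sqrt_psd(cov(xc))   # exact identity sample covariance
  expect_equal(ridge_whitening_estimate(xw, ridge = 0), diag(4),
               tolerance = 1e-8)
  W <- ridge_whitening_estimate(x0, ridge = 0.01)
  expect_equal(W, t(W), tolerance = 1e-10)
  expect_true(all(eigen(W, symmetric = TRUE)$values > 0))
  # huge ridge: transform collapses like ridge^{-1/2}
  Wbig <- ridge_whitening_estimate(x0, ridge = 1e8)
  expect_equal(Wbig, diag(4) / sqrt(1e8), tolerance = 1e-3)
})
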