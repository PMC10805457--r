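test_that("contrast vectors encode the centroid difference", {
  cv <- contrast_vector(c(1, 1, 2, 2, 3), 1, 2)
  expect_equal(cv$nu, c(1/2, 1/2, -1/2, -1/2, 0))
  expect_equal(sum(cv$nu), 0)
  expect_equal(cv$nu_norm2, sum(cv$nu^2))
  cv2 <- contrast_vector(c(1, 2), 1, 2)
  expect_equal(cv2$nu, c(1, -1))
  expect_equal(cv2$nu_norm2, 2)
  expect_error(contrast_vector(c(1, 1, 2), 1, 1), "must differ")
  expect_error(contrast_vector(c(1, 1, 2), 1, 3), "non-empty")
})

test_that("the perturbation line passes through the data and fixes the projection", {
  withr::with_seed(5, {
    x <- matrix(rnorm(30), 10, 3)
    cv <- contrast_vector(rep(1:2, 5), 1, 2)
    line <- perturbation_line(x, cv)
    expect_equal(perturbed_data(line, line$phi_obs), x, tolerance = 1e-12)
    Pi <- diag(10) - tcrossprod(cv$nu) / cv$nu_norm2
    for (phi in c(0, 0.7, 3, 12)) {
      xp <- perturbed_data(line, phi)
      expect_equal(Pi %*% xp, Pi %*% x, tolerance = 1e-10)
      # statistic of the perturbed data equals the coordinate
      expect_equal(sqrt(sum(crossprod(xp, cv$nu)^2)), phi, tolerance = 1e-9)
    }
  })
})

test_that("pairwise quadratics reproduce perturbed squared distances", {
  withr::with_seed(6, {
    x <- matrix(rnorm(24), 8, 3)
    cv <- contrast_vector(c(1, 1, 1, 2, 2, 3, 3, 3), 1, 2)
    line <- perturbation_line(x, cv)
    # same nu weight: constant polynomial equal to the data distance
    co <- pairwise_coeffs(line, 6, 7)
    expect_equal(unname(co), c(0, 0, sum((x[6, ] - x[7, ])^2)),
                 tolerance = 1e-9)
    for (pair in list(c(1, 4), c(2, 8), c(4, 5))) {
      co <- pairwise_coeffs(line, pair[1], pair[2])
      expect_equal(co[["a"]] * line$phi_obs^2 + co[["b"]] * line$phi_obs +
                     co[["c"]],
                   sum((x[pair[1], ] - x[pair[2], ])^2), tolerance = 1e-9)
      for (phi in seq(0, 8, length.out = 50)) {
        xp <- perturbed_data(line, phi)
        direct <- sum((xp[pair[1], ] - xp[pair[2], ])^2)
        poly <- co[["a"]] * phi^2 + co[["b"]] * phi + co[["c"]]
        expect_equal(poly, direct, tolerance = 1e-8)
      }
    }
  })
})

test_that("weighted-centroid quadratics reproduce perturbed distances", {
  withr::with_seed(8, {
    x <- matrix(rnorm(20), 10, 2)
    labels <- rep(1:2, each = 5)
    cv <- contrast_vector(labels, 1, 2)
    line <- perturbation_line(x, cv)
    # singleton weight on i itself: identically zero
    w <- numeric(10); w[3] <- 1
    expect_equal(unname(weighted_coeffs(line, 3, w)), c(0, 0, 0),
                 tolerance = 1e-12)
    # nu_i equal to the weighted nu average: leading coefficient vanishes
    w1 <- ifelse(labels == 1, 1/5, 0)
    co <- weighted_coeffs(line, 2, w1)
    expect_equal(co[["a"]], 0, tolerance = 1e-12)
    expect_error(weighted_coeffs(line, 1, rep(0.3, 10)), "sum to 1")
    # grid fidelity against direct computation
    w2 <- ifelse(labels == 2, 1/5, 0)
    for (i in c(1, 5, 9)) {
      co <- weighted_coeffs(line, i, w2)
      for (phi in seq(0, 6, length.out = 50)) {
        xp <- perturbed_data(line, phi)
        direct <- sum((xp[i, ] - drop(crossprod(xp, w2)))^2)
        expect_equal(co[["a"]] * phi^2 + co[["b"]] * phi + co[["c"]],
                     direct, tolerance = 1e-8)
      }
    }
  })
})

test_that("the constraint system has n*k*(T+1) rows, zero self rows, and holds at the data", {
  withr::with_seed(13, {
    x <- matrix(rnorm(36), 18, 2)
    tr <- kmeans_lloyd(x, 3, seed = 2)
    labels <- final_labels(tr)
    pair <- sort(unique(labels))[1:2]
    cv <- contrast_vector(labels, pair[1], pair[2])
    line <- perturbation_line(x, cv)
    cons <- build_constraints(line, tr)
    expect_identical(nrow(cons), 18L * 3L * (tr$iter + 1L))
    self <- cons$k == tr$assignments[cbind(cons$t + 1L, cons$i)]
    expect_true(all(cons$a[self] == 0 & cons$b[self] == 0 & cons$c[self] == 0))
    val <- cons$a * line$phi_obs^2 + cons$b * line$phi_obs + cons$c
    expect_true(all(val <= 1e-8))
  })
})

test_that("truncation regions contain the observed statistic and solve the event", {
  for (seed in 1:6) {
    x <- withr::with_seed(seed, matrix(rnorm(2 * 12), 12, 2))
    tr <- kmeans_lloyd(x, 2, seed = seed + 50)
    labels <- final_labels(tr)
    cv <- contrast_vector(labels, 1, 2)
    line <- perturbation_line(x, cv)
    reg <- truncation_region(line, tr)
    expect_true(iu_contains(line$phi_obs, reg, tol = 1e-8))
    expect_true(all(reg[, "lo"] >= 0))
    # re-clustering oracle agreement away from endpoints
    grid <- seq(0, line$phi_obs + 5 * sqrt(cv$nu_norm2), length.out = 120)
    ends <- as.numeric(reg)
    off <- !vapply(grid, function(g) any(abs(g - ends) < 1e-6), logical(1))
    mask <- grid_oracle_region(line, tr, grid)
    expect_identical(iu_contains(grid, reg)[off], mask[off])
  }
})

test_that("a single cluster leaves the region unconstrained", {
  x <- withr::with_seed(3, matrix(rnorm(16), 8, 2))
  tr <- kmeans_lloyd(x, 1, init = 1L)
  # contrast from an arbitrary split: with k = 1 no competitor constraints
  cv <- contrast_vector(rep(1:2, 4), 1, 2)
  line <- perturbation_line(x, cv)
  reg <- truncation_region(line, tr)
  expect_equal(as.numeric(reg), c(0, Inf))
  expect_true(all(grid_oracle_region(line, tr, seq(0, 10, 1))))
})
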