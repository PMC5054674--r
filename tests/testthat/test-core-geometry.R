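test_that("centering subtracts the centroid and is idempotent", {
  sq <- matrix(c(0, 0, 0, 2, 0, 0, 2, 2, 0, 0, 2, 0), ncol = 3, byrow = TRUE)
  cs <- center(sq)
  expect_equal(unclass(cs)[, 1:2], matrix(c(-1, 1, 1, -1, -1, -1, 1, 1), ncol = 2),
               ignore_attr = TRUE)
  expect_equal(colMeans(cs), c(0, 0, 0))
  expect_equal(as.matrix(center(cs)), as.matrix(cs))

  set.seed(1)
  big <- matrix(rnorm(1297 * 3, sd = 10), ncol = 3)
  expect_lt(max(abs(colMeans(center(big)))), 1e-12)

  big[1, 1] <- NA
  expect_error(center(big), "invalid input")
})

test_that("centroid size matches its definition and invariances", {
  sq <- matrix(c(-1, -1, 0, 1, -1, 0, 1, 1, 0, -1, 1, 0), ncol = 3, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(8))

  set.seed(2)
  x <- matrix(rnorm(60), ncol = 3)
  expect_equal(centroid_size(x * 3.7), 3.7 * centroid_size(x))
  r <- random_rotation()
  expect_equal(centroid_size(x %*% r), centroid_size(x), tolerance = 1e-10)
  expect_error(centroid_size(matrix(1, 5, 3)), "degenerate")
})

test_that("optimal rotation recovers known rotations and beats random search", {
  set.seed(3)
  x <- center(matrix(rnorm(90), ncol = 3))
  expect_equal(optimal_rotation(x, x), diag(3), tolerance = 1e-10)

  r <- random_rotation()
  moved <- x %*% r
  r_hat <- optimal_rotation(moved, x)
  expect_equal(r_hat, t(r), tolerance = 1e-8)
  expect_lt(sum((moved %*% r_hat - x)^2), 1e-16)

  # noisy pair: the closed-form solution is at least as good as 1000
  # random proper rotations
  y <- x %*% random_rotation() + matrix(rnorm(90, sd = 0.3), ncol = 3)
  y <- center(y)
  best <- sum((y %*% optimal_rotation(y, x) - x)^2)
  rand <- replicate(1000, sum((y %*% random_rotation() - x)^2))
  expect_lte(best, min(rand))

  expect_error(optimal_rotation(x, x[-1, ]), "mismatch")
})

test_that("GPA aligns rigidly moved copies exactly and averages two shapes", {
  set.seed(4)
  proto <- center(matrix(rnorm(45), ncol = 3))
  copies <- lapply(1:6, function(i)
    proto %*% random_rotation() + matrix(runif(3, -5, 5), nrow(proto), 3,
                                         byrow = TRUE))
  fit <- gpa(copies, space = "SSS")
  for (a in fit$aligned) expect_equal(a, fit$grand_mean, tolerance = 1e-8)
  expect_equal(fit$grand_mean, proto %*% optimal_rotation(proto, fit$grand_mean),
               tolerance = 1e-8)

  two <- list(proto, proto + matrix(rnorm(45, sd = 0.2), ncol = 3))
  fit2 <- gpa(lapply(two, center), space = "SSS")
  expect_equal(fit2$grand_mean, (fit2$aligned[[1]] + fit2$aligned[[2]]) / 2)
})

test_that("SSS GPA preserves sizes, decreases its objective, and is rigid-motion invariant", {
  set.seed(5)
  configs <- lapply(1:8, function(i) matrix(rnorm(60, sd = 3), ncol = 3))
  fit <- gpa(configs, space = "SSS")
  cs_in <- vapply(configs, centroid_size, 0)
  cs_out <- vapply(fit$aligned, centroid_size, 0)
  expect_equal(cs_out, cs_in, tolerance = 1e-9)
  expect_true(all(vapply(fit$aligned, function(a) max(abs(colMeans(a))), 0) < 1e-10))
  expect_true(all(vapply(fit$rotations, det, 0) > 0.999))
  expect_true(all(diff(fit$objective) <= 1e-10))

  # one common rigid motion applied to every input leaves aligned
  # inter-configuration distances unchanged
  r <- random_rotation(); tr <- runif(3, -10, 10)
  moved <- lapply(configs, function(x) sweep(x %*% r, 2, tr, `+`))
  fit_m <- gpa(moved, space = "SSS")
  d <- function(f) as.matrix(dist(lamorph:::vectorize_configs(f$aligned)))
  expect_equal(d(fit_m), d(fit), tolerance = 1e-8)
})

test_that("SS GPA scales configurations to unit centroid size", {
  set.seed(6)
  configs <- lapply(1:5, function(i) matrix(rnorm(36, sd = i), ncol = 3))
  fit <- gpa(configs, space = "SS")
  expect_equal(vapply(fit$aligned, centroid_size, 0), rep(1, 5),
               tolerance = 1e-9)
})

test_that("shape PCA recovers planar structure and reconstructs losslessly", {
  set.seed(7)
  base <- center(matrix(rnorm(30), ncol = 3))
  d1 <- center(matrix(rnorm(30), ncol = 3))
  d2 <- center(matrix(rnorm(30), ncol = 3))
  configs <- lapply(1:12, function(i)
    base + rnorm(1) * d1 + rnorm(1) * d2)     # exact 2-plane in config space
  pca <- shape_pca(configs)
  expect_equal(sum(pca$eigenvalues > 1e-10 * pca$eigenvalues[1]), 2)
  expect_equal(sum(pca$variance_fraction), 1)
  expect_equal(pca$cumulative_fraction[3],
               sum(pca$variance_fraction[1:3]))
  expect_true(all(diff(pca$cumulative_fraction) >= -1e-12))

  # eigenvalue sum equals total variance of the vectorized data
  dat <- lamorph:::vectorize_configs(configs)
  expect_equal(sum(pca$eigenvalues), sum(apply(dat, 2, var)))
  # scores are centered; loadings orthonormal
  expect_lt(max(abs(colMeans(pca$scores))), 1e-10)
  expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)),
               tolerance = 1e-10)
  # lossless reconstruction with all components
  rec <- pca_reconstruct(pca, pca$scores)
  for (i in seq_along(configs))
    expect_equal(rec[[i]], configs[[i]], tolerance = 1e-8)

  expect_error(shape_pca(configs[1]), "insufficient")
})
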