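test_that("permutation ANOVA matches the point-biserial closed form and is seeded", {
  set.seed(41)
  g <- rep(c("a", "b"), c(12, 9))
  y <- rnorm(21) + (g == "b") * 0.8
  res <- perm_anova(y, g, n_perm = 499, seed = 5)
  expect_equal(res$r_squared, cor(y, as.numeric(g == "b"))^2)
  expect_identical(perm_anova(y, g, n_perm = 499, seed = 5)$p_value,
                   res$p_value)
  expect_false(perm_anova(y, g, n_perm = 499, seed = 6)$p_value == 0)

  # perfectly separated groups: no permutation beats the observed split
  y2 <- c(rnorm(10), rnorm(10) + 100)
  res2 <- perm_anova(y2, rep(c("a", "b"), each = 10), n_perm = 999, seed = 1)
  expect_equal(res2$p_value, 1 / 1000)
  expect_error(perm_anova(rep(1, 20), rep(c("a", "b"), each = 10)),
               "undefined R-squared")
})

test_that("trace MANOVA reduces to ANOVA, ignores duplicated columns, and matches adonis2", {
  set.seed(42)
  g <- rep(c("a", "b"), each = 10)
  y <- rnorm(20) + (g == "b")
  uni <- perm_anova(y, g, n_perm = 199, seed = 3)
  multi <- perm_manova(matrix(y, ncol = 1), g, n_perm = 199, seed = 3)
  expect_equal(multi$r_squared, uni$r_squared)
  expect_equal(multi$p_value, uni$p_value)

  Y <- matrix(rnorm(60), 20, 3) + (g == "b")
  r1 <- perm_manova(Y, g, n_perm = 99, seed = 1)$r_squared
  r2 <- perm_manova(cbind(Y, Y), g, n_perm = 99, seed = 1)$r_squared
  expect_equal(r1, r2)

  # independent oracle: distance-based partitioning with Euclidean distances
  ad <- vegan::adonis2(dist(Y) ~ g, permutations = 99)
  expect_equal(r1, ad$R2[1], tolerance = 1e-10)
})

test_that("permutation p-values are calibrated under the null", {
  reps <- 300
  p <- vapply(seq_len(reps), function(i) {
    set.seed(i)
    y <- rnorm(20)
    perm_anova(y, rep(c("a", "b"), each = 10), n_perm = 199,
               seed = 1000 + i)$p_value
  }, 0)
  expect_gte(mean(p < 0.05), 0.02 - 0.02)   # not degenerate
  expect_lte(mean(p < 0.05), 0.09)
  # Kolmogorov-Smirnov sanity: null p-values are close to uniform
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("spearman correlation handles monotone, reversed and noisy data", {
  x <- 1:20
  expect_equal(spearman_cor(x, x^3 + 2)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  expect_lt(spearman_cor(x, x^2, n_perm = 499, seed = 2)$p_value, 0.01)

  set.seed(43)
  n <- 200
  z <- rnorm(n)
  y <- 0.58 * z + sqrt(1 - 0.58^2) * rnorm(n)   # rank corr about 0.56
  est <- spearman_cor(z, y, n_perm = 199, seed = 4)$rho
  expect_lt(abs(est - 0.56), 0.1)
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("mean-centered correlation removes between-subject offsets", {
  set.seed(44)
  subj <- rep(paste0("s", 1:10), each = 12)
  pattern <- sin(2 * pi * (0:11) / 12)
  x <- rep(pattern, 10) + rnorm(120, sd = 0.1)
  offsets <- rep(rnorm(10, sd = 50), each = 12)
  y <- 0.9 * rep(pattern, 10) + rnorm(120, sd = 0.1)
  r_plain <- mean_centered_correlation(x + offsets, y + offsets, subj)$rho
  r_clean <- mean_centered_correlation(x, y, subj)$rho
  expect_equal(r_plain, r_clean, tolerance = 1e-10)
  expect_gt(r_plain, 0.9)

  # pure between-subject association, no within-subject association
  xb <- rep(rnorm(10), each = 12) + rnorm(120, sd = 0.05)
  yb <- rep(10 * tapply(xb, subj, mean)[paste0("s", 1:10)], each = 12) +
    rnorm(120, sd = 0.05)
  expect_lt(abs(mean_centered_correlation(xb, yb, subj)$rho), 0.25)

  # centering twice is idempotent
  xc <- x - ave(x, subj)
  expect_equal(xc - ave(xc, subj), xc)
})

test_that("observed R-squared grows with the simulated effect size", {
  set.seed(45)
  g <- rep(c("a", "b"), each = 15)
  mean_r2 <- vapply(c(0, 0.5, 1.5, 3), function(delta)
    mean(vapply(1:20, function(i) {
      y <- rnorm(30) + (g == "b") * delta
      perm_anova(y, g, n_perm = 99, seed = i)$r_squared
    }, 0)), 0)
  expect_true(all(diff(mean_r2) > 0))
})

test_that("per-time tests report MANOVA and per-PC profiles for all 12 times", {
  run <- tiny_run()
  tests <- per_time_tests(run$dpca, n_pcs = 5, n_perm = 99, seed = 2)
  expect_equal(tests$manova$time_index, 1:12)
  expect_true(all(tests$manova$r_squared >= 0 & tests$manova$r_squared <= 1))
  expect_equal(nrow(tests$univariate), 12L * 5L)
  adj <- per_time_tests(run$dpca, n_pcs = 5, n_perm = 99, seed = 2,
                        adjust = "BH")
  expect_true(all(adj$univariate$p_value >= tests$univariate$p_value - 1e-12))
})
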