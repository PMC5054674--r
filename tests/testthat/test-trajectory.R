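# random similarity transform of a 12 x q trajectory
sim_transform <- function(p, q = ncol(p)) {
  r <- random_rotation(q)
  s <- runif(1, 0.3, 3)
  tr <- matrix(runif(q, -4, 4), nrow(p), q, byrow = TRUE)
  s * p %*% r + tr
}

test_that("trajectories are the leading deformation PC scores, row-per-time", {
  set.seed(21)
  sc <- matrix(rnorm(12 * 10), 12, 10)
  tr <- build_trajectory(sc, q = 3)
  expect_equal(tr$points, sc[, 1:3])
  expect_equal(dim(build_trajectory(sc, q = 10)$points), c(12L, 10L))
  expect_error(build_trajectory(sc[-1, ], q = 3), "incomplete")
  expect_error(build_trajectory(sc, q = 11), "incomplete")

  run <- tiny_run()
  trajs <- cohort_trajectories(run$dpca, q = 3)
  expect_length(trajs, length(run$cohort))
  id <- trajs[[3]]$subject_id
  rows <- run$dpca$index$subject_id == id
  expect_equal(trajs[[3]]$points,
               run$dpca$pca$scores[rows, 1:3])
})

test_that("anchor-only GPA aligns similarity-transformed copies exactly", {
  set.seed(22)
  proto <- matrix(rnorm(36), 12, 3)
  trajs <- lapply(1:5, function(i)
    build_trajectory(cbind(sim_transform(proto), matrix(0, 12, 0)),
                     subject_id = paste0("s", i)))
  fit <- trajectory_gpa(trajs)
  for (a in fit$aligned) expect_equal(a, fit$mean_trajectory,
                                      tolerance = 1e-8)
})

test_that("passive landmarks do not influence the anchor-only fit", {
  set.seed(23)
  trajs <- lapply(1:6, function(i)
    build_trajectory(matrix(rnorm(36), 12, 3), subject_id = paste0("s", i)))
  fit <- trajectory_gpa(trajs, anchors = c(1, 5, 9))

  # perturb only non-anchor landmarks of every trajectory
  passive <- setdiff(1:12, c(1, 5, 9))
  trajs2 <- lapply(trajs, function(tr) {
    tr$points[passive, ] <- tr$points[passive, ] + rnorm(length(passive) * 3)
    tr
  })
  fit2 <- trajectory_gpa(trajs2, anchors = c(1, 5, 9))
  for (i in seq_along(trajs)) {
    expect_equal(fit2$aligned[[i]][c(1, 5, 9), ],
                 fit$aligned[[i]][c(1, 5, 9), ], tolerance = 1e-8)
  }
  expect_error(trajectory_gpa(trajs, anchors = c(1, 5)),
               "under-determined")
})

test_that("anchor alignment beats random similarity transforms on anchor distance", {
  set.seed(24)
  trajs <- lapply(1:2, function(i)
    build_trajectory(matrix(rnorm(36), 12, 3), subject_id = paste0("s", i)))
  fit <- trajectory_gpa(trajs)
  anchors <- c(1, 5, 9)
  d_fit <- sum((fit$aligned[[1]][anchors, ] - fit$aligned[[2]][anchors, ])^2)

  # oracle: the second trajectory under 1000 random similarity transforms,
  # each normalized the same way (anchor centroid/size of the first fixed)
  a1 <- fit$aligned[[1]]
  d_rand <- replicate(1000, {
    p2 <- sim_transform(trajs[[2]]$points)
    p2 <- sweep(p2, 2, colMeans(p2[anchors, ]))
    p2 <- p2 / sqrt(sum(p2[anchors, ]^2))
    sum((a1[anchors, ] - p2[anchors, ])^2)
  })
  expect_lte(d_fit, min(d_rand) + 1e-12)
})

test_that("trajectory size scales linearly and rejects degenerate paths", {
  set.seed(25)
  p <- matrix(rnorm(36), 12, 3)
  expect_equal(trajectory_size(2 * p), 2 * trajectory_size(p))
  expect_error(trajectory_size(matrix(1, 12, 3)), "degenerate")
})

test_that("orientation angles follow the atan2 convention in degrees", {
  base <- matrix(0, 12, 3)
  mk <- function(v) { p <- base; p[5, ] <- v; p }
  expect_equal(trajectory_orientation(mk(c(1, 0, 0))),
               c(angle_12 = 0, angle_13 = 0))
  expect_equal(trajectory_orientation(mk(c(0, 1, 0)))[["angle_12"]], 90)
  expect_equal(trajectory_orientation(mk(c(-1, -1, 0)))[["angle_12"]], -135)
  expect_equal(trajectory_orientation(mk(c(1, 0, -1)))[["angle_13"]], -45)
  expect_error(trajectory_orientation(base), "undefined orientation")
})

test_that("a localized bend difference loads trajectory-shape PC1 on the bent landmarks", {
  set.seed(26)
  # two clusters: identical except a bend at landmarks 6-9
  proto <- cbind(cos(2 * pi * (0:11) / 12), sin(2 * pi * (0:11) / 12), 0)
  bend <- matrix(0, 12, 3); bend[6:9, 3] <- c(0.5, 1, 1, 0.5)
  trajs <- c(
    lapply(1:8, function(i) build_trajectory(
      proto + bend + matrix(rnorm(36, sd = 0.05), 12, 3),
      subject_id = paste0("c", i), group = "Control")),
    lapply(1:8, function(i) build_trajectory(
      proto + matrix(rnorm(36, sd = 0.05), 12, 3),
      subject_id = paste0("h", i), group = "HCM")))
  fit <- trajectory_gpa(trajs)
  pca <- trajectory_shape_pca(fit)
  # squared PC1 loading mass concentrated on landmarks 6-9
  l1 <- matrix(pca$loadings[, 1], 12, 3)
  expect_gte(sum(l1[6:9, ]^2) / sum(l1^2), 0.5)

  expect_lt(abs(sum(pca$loadings[, 1] * pca$loadings[, 2])), 1e-10)
})

test_that("trajectory attribute table carries shape PCs, size and angles", {
  run <- tiny_run()
  trajs <- cohort_trajectories(run$dpca, q = 3)
  attrs <- trajectory_attributes(trajs, n_components = 5)
  expect_equal(nrow(attrs$table), length(run$cohort))
  expect_true(all(c("shape_pc1", "size", "angle_12", "angle_13") %in%
                  names(attrs$table)))
  expect_true(all(attrs$table$size > 0))
  expect_true(all(attrs$table$angle_12 > -180 & attrs$table$angle_12 <= 180))
})
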