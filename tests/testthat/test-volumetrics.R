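test_that("mesh volume approximates an analytic sphere and converges with resolution", {
  true_ml <- 4 / 3 * pi * 20^3 / 1000
  errs <- vapply(c(9, 18, 36, 72), function(n) {
    v <- mesh_volume(sphere_config(n, n))
    abs(v - true_ml) / true_ml
  }, 0)
  expect_lt(errs[3], 0.01)            # 36 x 36 within 1%
  expect_true(all(diff(errs) < 0))    # refining the grid shrinks the error
})

test_that("mesh volume is homogeneous of degree 3 and rigid-motion invariant", {
  set.seed(31)
  cfg <- la_template(12, 12)
  v <- mesh_volume(cfg)
  expect_gt(v, 0)
  expect_equal(mesh_volume(2 * as.matrix(cfg), rings = 12,
                           points_per_ring = 12), 8 * v)
  moved <- sweep(as.matrix(cfg) %*% random_rotation(), 2, c(5, -3, 7), `+`)
  expect_equal(mesh_volume(moved, rings = 12, points_per_ring = 12), v,
               tolerance = 1e-10)
  # half-ellipsoid template: analytic volume (2/3) pi a^2 c
  expect_equal(mesh_volume(la_template(72, 72)),
               2 / 3 * pi * 20^2 * 40 / 1000, tolerance = 0.01)
})

test_that("phasic indicators follow the stated formulas", {
  v <- c(35, 45, 55, 59, 60, 55, 48, 42, 40, 36, 31, 32)  # vmax 60 at ED,
  ind <- la_function_indicators(v)                         # preA 40, vmin 31
  expect_equal(ind$v_max, 60)
  expect_equal(ind$v_preA, 40)
  expect_equal(ind$ef_global, 100 * (60 - 31) / 60)
  expect_equal(ind$ef_conduit, 100 * (60 - 40) / 60)
  expect_equal(ind$ef_booster, 100 * (40 - 31) / 40)
  expect_equal(ind$booster_abs, 9)

  # worked triple (vmax 60, vmin 30, vpreA 40)
  v2 <- c(32, 40, 50, 57, 60, 55, 50, 45, 40, 34, 30, 31)
  ind2 <- la_function_indicators(v2)
  expect_equal(ind2$ef_global, 50)
  expect_equal(ind2$ef_conduit, 100 / 3, tolerance = 1e-10)
  expect_equal(ind2$ef_booster, 25)
  expect_equal(ind2$booster_abs, 10)

  flat <- la_function_indicators(rep(42, 12))
  expect_equal(flat$ef_global, 0)
  expect_equal(flat$ef_reservoir, 0)
  expect_equal(flat$booster_abs, 0)
})

test_that("EF identity holds on random admissible curves", {
  set.seed(32)
  for (i in 1:25) {
    v <- runif(12, 20, 40)
    v[5] <- max(v) + runif(1, 0.5, 5)          # vmax at ED
    ind <- suppressWarnings(la_function_indicators(v))
    expect_equal(ind$ef_global * ind$v_max,
                 ind$ef_conduit * ind$v_max + 100 * ind$booster_abs)
  }
})

test_that("classic global strains are zero at end-systole and track scaling", {
  cfg <- la_template(10, 10)
  mk_series <- function(factors) {
    shapes <- lapply(factors, function(f)
      landmark_config(as.matrix(cfg) * f, rings = 10, points_per_ring = 10))
    structure(list(shapes = shapes,
                   homologous_times = seq(0, 1100, by = 100),
                   subject_id = "s", group = "Control"),
              class = "homologous_series")
  }
  f <- c(1.08, 1.1, 1.12, 1.1, 1.15, 1.1, 1.05, 1.02, 1.01, 1, 1.02, 1.04)
  cp <- classic_global_parameters(mk_series(f))
  es <- which.min(cp$volume_ml)
  expect_equal(es, which.min(f))
  expect_equal(cp$gls[es], 0)
  expect_equal(cp$gcs[es], 0)
  # uniform dilation by 1.1 relative to ES: both strains +10%
  i11 <- which(abs(f - 1.1) < 1e-12)[1]
  expect_equal(cp$gls[i11], 10, tolerance = 1e-8)
  expect_equal(cp$gcs[i11], 10, tolerance = 1e-8)
  # strain extrema co-occur with the volume extremum
  expect_equal(which.max(cp$gls), which.max(cp$volume_ml))
})

test_that("indicators are invariant to rigid motion of every frame", {
  spec <- small_spec(n_control = 2L, n_case = 0L, seed = 77L)
  cohort <- generate_cohort(spec)
  hom <- homologize_cohort(cohort)
  s <- hom$series[[1]]
  ind <- la_function_indicators(volume_curve(s))
  set.seed(33)
  r <- random_rotation()
  s2 <- s
  s2$shapes <- lapply(s$shapes, function(x)
    landmark_config(sweep(as.matrix(x) %*% r, 2, c(10, 5, -4), `+`),
                    rings = 12, points_per_ring = 12))
  ind2 <- la_function_indicators(volume_curve(s2))
  expect_equal(ind2$ef_global, ind$ef_global, tolerance = 1e-10)
  expect_equal(ind2$v_max, ind$v_max, tolerance = 1e-10)
})
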