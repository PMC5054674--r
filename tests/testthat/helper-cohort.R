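# Shared fixtures, built in code. Expensive cohorts are cached across test
# files within one test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small-geometry spec: 12 x 12 + apex = 145 landmarks
small_spec <- function(...) {
  cohort_spec(rings = 12L, points_per_ring = 12L, ...)
}

# a tiny mixed cohort and its homologized/deformation stages
tiny_run <- function() {
  cached("tiny_run", {
    spec <- small_spec(n_control = 6L, n_case = 6L, seed = 421L)
    cohort <- generate_cohort(spec)
    hom <- homologize_cohort(cohort)
    dpca <- deformation_analysis(hom$series)
    list(spec = spec, cohort = cohort, hom = hom, dpca = dpca)
  })
}

random_rotation <- function(m = 3L) {
  q <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# full-sphere landmark cloud on the ring/apex topology: rings of latitude
# from near the north pole (open base, centroid-capped) to near the south
# pole, plus the south-pole apex
sphere_config <- function(rings, points, r = 20) {
  th <- (seq_len(rings) - 0.5) / rings * pi
  ph <- 2 * pi * (seq_len(points) - 1L) / points
  x <- do.call(rbind, lapply(th, function(t)
    cbind(r * sin(t) * cos(ph), r * sin(t) * sin(ph), r * cos(t))))
  landmark_config(rbind(x, c(0, 0, -r)), rings = rings,
                  points_per_ring = points)
}
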