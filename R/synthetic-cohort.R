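#' Specification of a synthetic two-group LA cohort
#'
#' Parameters of the synthetic 3DSTE-like cohort generator. Defaults
#' emulate the study conditions of a Control vs non-obstructive HCM
#' comparison: 46 controls and 22 cases; case LA volumes more than twofold
#' dilated; global, reservoir and conduit emptying reduced in cases while
#' the absolute booster volume is increased; and a pre-P-peak flattening
#' (diastasis plateau) of the volume curve present in controls and absent
#' in cases, which is what bends the deformation trajectory at the
#' homologous landmarks between end-diastole and the P peak.
#'
#' @param n_control,n_case group sizes (46 / 22).
#' @param rings,points_per_ring endocardial sampling topology (36 x 36 + apex
#'   = 1297 landmarks).
#' @param base_volume_ml control maximal LA volume (ml); 60 ml is a typical
#'   adult LA end-diastolic volume.
#' @param case_dilation_factor case v_max multiplier (default 2.2, "more
#'   than twofold" dilation).
#' @param ef_global_control,ef_global_case target global (total) emptying
#'   fractions, % (50 vs 30: preserved-vs-impaired total emptying).
#' @param preA_fraction_control,preA_fraction_case position of the
#'   pre-atrial-contraction volume between v_min and v_max (0.35 vs 0.55:
#'   together with dilation this yields reduced conduit EF and increased
#'   absolute booster volume in cases).
#' @param bend_amplitude_control,bend_amplitude_case strength in [0, 1] of
#'   the conduit-phase flattening before the P peak (0.8 vs 0).
#' @param twist_deg_control,twist_deg_case peak systolic twist about the
#'   long axis, degrees (8 vs 3: reduced torsion in cases).
#' @param inter_subject_shape_sd RMS amplitude (mm) of the smooth
#'   subject-specific static shape perturbation.
#' @param landmark_noise_sd i.i.d. per-landmark measurement noise sd (mm).
#' @param frame_rate_range volumetric acquisition rate range (Hz), sampled
#'   per subject.
#' @param cycle_ms_range cardiac cycle length range (ms), sampled per
#'   subject (roughly 63-92 bpm).
#' @param seed master seed; every generated quantity is a pure function of
#'   (spec, seed).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 46L, n_case = 22L,
                        rings = 36L, points_per_ring = 36L,
                        base_volume_ml = 60, case_dilation_factor = 2.2,
                        ef_global_control = 50, ef_global_case = 30,
                        preA_fraction_control = 0.35,
                        preA_fraction_case = 0.55,
                        bend_amplitude_control = 0.8,
                        bend_amplitude_case = 0,
                        twist_deg_control = 8, twist_deg_case = 3,
                        inter_subject_shape_sd = 2,
                        landmark_noise_sd = 0.2,
                        frame_rate_range = c(20, 35),
                        cycle_ms_range = c(650, 950),
                        seed = 20161007L) {
  spec <- as.list(environment())
  if (n_control < 0 || n_case < 0) stop("invalid spec: negative group size")
  if (base_volume_ml <= 0 || case_dilation_factor <= 0)
    stop("invalid spec: volumes and factors must be positive")
  for (ef in c(ef_global_control, ef_global_case))
    if (ef <= 0 || ef >= 100) stop("invalid spec: infeasible ejection fraction")
  if (landmark_noise_sd < 0 || inter_subject_shape_sd < 0)
    stop("invalid spec: negative noise")
  structure(spec, class = "cohort_spec")
}

#' Idealised LA endocardial template
#'
#' Half-ellipsoid cup sampled on the ring/apex topology: `rings` horizontal
#' circles of `points_per_ring` landmarks from the open base ring (the
#' mitral plane, z = 0) towards the apex, plus the apex point. With the
#' defaults (36 x 36 + apex) this gives the 1297-landmark sampling of the
#' endocardial surface.
#'
#' @param rings,points_per_ring grid size (each >= 4).
#' @param a,c_ax radial and long-axis semi-axes (mm).
#' @return a [landmark_config()] with topology attributes.
#' @export
la_template <- function(rings = 36L, points_per_ring = 36L, a = 20, c_ax = 40) {
  if (rings < 4L || points_per_ring < 4L) stop("need rings, points >= 4")
  theta <- (seq_len(rings) - 1L) / rings * (pi / 2)   # 0 = base ring
  phi <- 2 * pi * (seq_len(points_per_ring) - 1L) / points_per_ring
  coords <- do.call(rbind, lapply(theta, function(th)
    cbind(a * cos(th) * cos(phi), a * cos(th) * sin(phi),
          -c_ax * sin(th))))
  coords <- rbind(coords, c(0, 0, -c_ax))
  landmark_config(coords, rings = rings, points_per_ring = points_per_ring)
}

#' Per-subject LA volume program
#'
#' Smooth periodic volume-vs-time function for one synthetic subject:
#' reservoir rise to v_max at LA end-diastole, conduit fall with an
#' optional pre-P-peak plateau of strength `bend` (the diastasis
#' flattening), booster drop to v_min after the P peak, and a small
#' early-systolic refill back to the R-peak volume. Event times and phasic
#' targets are jittered per subject; the function is periodic with the
#' sampled cycle length. Must be called inside a seeded RNG context (the
#' generator does this).
#'
#' @param group `"Control"` or `"HCM"`.
#' @param spec a [cohort_spec()].
#' @return list: `fn` (vectorized volume function of time in ms),
#'   `events` (an [event_annotations()] for cycle one), `cycle_ms`,
#'   `v_max`, `v_min`, `v_preA`, `ef_global`, `bend`.
#' @export
volume_program <- function(group, spec) {
  is_case <- group == "HCM"
  cycle <- runif(1, spec$cycle_ms_range[1L], spec$cycle_ms_range[2L])
  # event fractions of the cycle, jittered per subject
  f_ed <- 0.40 + rnorm(1, 0, 0.02)
  f_p <- 0.85 + rnorm(1, 0, 0.015)
  t_ed <- cycle * min(max(f_ed, 0.3), 0.5)
  t_p <- cycle * min(max(f_p, 0.78), 0.92)

  v_max <- spec$base_volume_ml *
    (if (is_case) spec$case_dilation_factor else 1) * exp(rnorm(1, 0, 0.08))
  ef <- (if (is_case) spec$ef_global_case else spec$ef_global_control) +
    min(max(rnorm(1, 0, 0.4), -0.9), 0.9)
  if (ef <= 0 || ef >= 100) stop("invalid spec: infeasible ejection fraction")
  v_min <- v_max * (1 - ef / 100)
  rho <- (if (is_case) spec$preA_fraction_case else
          spec$preA_fraction_control) + min(max(rnorm(1, 0, 0.03), -0.1), 0.1)
  v_preA <- v_min + rho * (v_max - v_min)
  bend <- if (is_case) spec$bend_amplitude_case else spec$bend_amplitude_control
  v_r <- v_min + 0.05 * (v_max - v_min)

  fn <- function(t) {
    tm <- t %% cycle
    v <- numeric(length(tm))
    s1 <- tm <= t_ed
    s <- tm[s1] / t_ed
    v[s1] <- v_r + (v_max - v_r) * (1 - cos(pi * s)) / 2
    s2 <- tm > t_ed & tm <= t_p
    s <- (tm[s2] - t_ed) / (t_p - t_ed)
    descent <- (1 - bend) * s + bend * s^2 * (3 - 2 * s)
    v[s2] <- v_max - (v_max - v_preA) * descent
    s3 <- tm > t_p
    s <- (tm[s3] - t_p) / (cycle - t_p)
    drop_ <- s <= 0.7
    v3 <- numeric(sum(s3))
    v3[drop_] <- v_preA + (v_min - v_preA) *
      (1 - cos(pi * s[drop_] / 0.7)) / 2
    v3[!drop_] <- v_min + (v_r - v_min) *
      (1 - cos(pi * (s[!drop_] - 0.7) / 0.3)) / 2
    v[s3] <- v3
    v
  }
  list(fn = fn, events = event_annotations(0, t_ed, t_p, cycle),
       cycle_ms = cycle, v_max = v_max, v_min = v_min, v_preA = v_preA,
       ef_global = ef, bend = bend)
}

# Smooth low-order static shape perturbation: a random linear (affine)
# field plus low-frequency trigonometric radial bumps, rescaled to a
# target RMS landmark displacement. Deliberately non-physiological — it
# exists to inject inter-subject shape variance, not anatomy.
subject_perturbation <- function(template, target_rms) {
  x <- as_coord_matrix(template)
  if (target_rms == 0) return(matrix(0, nrow(x), ncol(x)))
  A <- matrix(rnorm(9L, 0, 1), 3L, 3L)
  d <- x %*% A
  topo <- config_topology(template)
  P <- topo$points_per_ring; R <- topo$rings
  u <- c(rep((seq_len(R) - 1L) / R, each = P), 1)        # base->apex fraction
  phi <- c(rep(2 * pi * (seq_len(P) - 1L) / P, R), 0)
  radial <- x / pmax(sqrt(rowSums(x^2)), 1e-9)
  for (h in 1:2) {
    amp <- rnorm(2L, 0, 1)
    d <- d + radial * (amp[1L] * cos(h * phi) * sin(pi * u) +
                       amp[2L] * sin(h * phi) * sin(pi * u)) * 10
  }
  d * target_rms / sqrt(mean(rowSums(d^2)))
}

#' Generate one synthetic subject
#'
#' Deforms the template frame by frame so that the mesh volume tracks the
#' subject's volume program: an anisotropic similarity field (long-axis
#' shortening plus circumferential narrowing, exponents 0.4/0.3 of the
#' volume ratio), a twist about the long axis growing with contraction, a
#' smooth static subject-specific shape perturbation, and i.i.d. landmark
#' noise. Two full cycles are generated; analyses consume cycle one.
#'
#' @param group `"Control"` or `"HCM"`.
#' @param spec a [cohort_spec()].
#' @param seed subject seed.
#' @param subject_id id string.
#' @return a [cine_sequence()]; the generating program is attached as
#'   attribute `program`.
#' @export
generate_subject <- function(group, spec, seed, subject_id = "S1") {
  with_seed(seed, {
    prog <- volume_program(group, spec)
    template <- la_template(spec$rings, spec$points_per_ring)
    pert <- subject_perturbation(template, spec$inter_subject_shape_sd)
    base_shape <- as_coord_matrix(template) + pert
    v0 <- mesh_volume(base_shape, rings = spec$rings,
                      points_per_ring = spec$points_per_ring)
    twist <- if (group == "HCM") spec$twist_deg_case else spec$twist_deg_control

    topo <- config_topology(template)
    u <- c(rep((seq_len(topo$rings) - 1L) / topo$rings,
               each = topo$points_per_ring), 1)

    fr <- runif(1, spec$frame_rate_range[1L], spec$frame_rate_range[2L])
    times <- seq(0, 2 * prog$cycle_ms, by = 1000 / fr)
    if (max(times) < prog$cycle_ms) times <- c(times, prog$cycle_ms)

    k <- nrow(base_shape)
    frames <- lapply(times, function(t) {
      v <- prog$fn(t)
      g <- v / v0
      lz <- g^0.4                      # long-axis share of the volume change
      lr <- g^0.3                      # circumferential share (lr^2 * lz = g)
      xyz <- base_shape
      xyz[, 1L] <- xyz[, 1L] * lr
      xyz[, 2L] <- xyz[, 2L] * lr
      xyz[, 3L] <- xyz[, 3L] * lz
      ang <- twist * (1 - v / prog$v_max) * u * pi / 180
      ca <- cos(ang); sa <- sin(ang)
      xr <- xyz[, 1L] * ca - xyz[, 2L] * sa
      yr <- xyz[, 1L] * sa + xyz[, 2L] * ca
      xyz[, 1L] <- xr; xyz[, 2L] <- yr
      if (spec$landmark_noise_sd > 0)
        xyz <- xyz + matrix(rnorm(3L * k, 0, spec$landmark_noise_sd), k, 3L)
      landmark_config(xyz, rings = spec$rings,
                      points_per_ring = spec$points_per_ring)
    })
    cine <- cine_sequence(frames, times, prog$events, subject_id,
                          group = group)
    attr(cine, "program") <- prog[c("cycle_ms", "v_max", "v_min", "v_preA",
                                    "ef_global", "bend")]
    attr(cine, "volume_fn") <- prog$fn
    cine
  })
}

#' Generate a labelled synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of [cine_sequence()] objects (controls first, ids
#'   `C01...`, then cases `H01...`), reproducible from `spec$seed`.
#' @export
generate_cohort <- function(spec) {
  ctrl <- lapply(seq_len(spec$n_control), function(i)
    generate_subject("Control", spec, seed = spec$seed + i,
                     subject_id = sprintf("C%02d", i)))
  case <- lapply(seq_len(spec$n_case), function(i)
    generate_subject("HCM", spec, seed = spec$seed + 100000L + i,
                     subject_id = sprintf("H%02d", i)))
  c(ctrl, case)
}
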