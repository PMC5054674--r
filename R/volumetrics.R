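# Triangulation of the ring/apex LA surface (1-based vertex indices into
# the landmark matrix; the base ring is capped by a centroid fan, the last
# ring is closed onto the apex). Cached per topology.
.tri_cache <- new.env(parent = emptyenv())

ring_apex_triangles <- function(rings, points_per_ring) {
  key <- paste(rings, points_per_ring, sep = "x")
  if (!is.null(.tri_cache[[key]])) return(.tri_cache[[key]])
  P <- points_per_ring
  idx <- function(r, p) (r - 1L) * P + ((p - 1L) %% P) + 1L
  tri <- vector("list", 3L)
  # bands between consecutive rings: two triangles per quad
  r <- rep(seq_len(rings - 1L), each = P)
  p <- rep(seq_len(P), rings - 1L)
  tri[[1L]] <- cbind(idx(r, p), idx(r, p + 1L), idx(r + 1L, p + 1L))
  tri[[2L]] <- cbind(idx(r, p), idx(r + 1L, p + 1L), idx(r + 1L, p))
  # apex fan closing the last ring onto the apex vertex
  apex <- rings * P + 1L
  p <- seq_len(P)
  tri[[3L]] <- cbind(idx(rings, p), idx(rings, p + 1L), apex)
  out <- do.call(rbind, tri)
  .tri_cache[[key]] <- out
  out
}

#' Cavity volume of a ring/apex landmark surface
#'
#' Volume (ml) of the closed surface obtained by triangulating adjacent
#' rings, closing the last ring onto the apex, and capping the open base
#' ring (the mitral plane) with a fan to its centroid. Computed as the sum
#' of signed tetrahedra against the origin (divergence theorem); the sign
#' is corrected so the returned volume is positive.
#'
#' @param config landmark matrix (mm) with ring/apex topology attributes,
#'   or a plain matrix plus explicit `rings`/`points_per_ring`.
#' @param rings,points_per_ring topology override when `config` carries
#'   none.
#' @return volume in ml (mm^3 / 1000).
#' @export
mesh_volume <- function(config, rings = NULL, points_per_ring = NULL) {
  topo <- config_topology(config)
  rings <- rings %||% topo$rings
  points_per_ring <- points_per_ring %||% topo$points_per_ring
  if (is.null(rings) || is.null(points_per_ring))
    stop("mesh_volume needs the ring/apex topology")
  x <- as_coord_matrix(config)
  if (nrow(x) != rings * points_per_ring + 1L)
    stop("topology mismatch: wrong landmark count")
  tri <- ring_apex_triangles(rings, points_per_ring)
  a <- x[tri[, 1L], , drop = FALSE]
  b <- x[tri[, 2L], , drop = FALSE]
  c_ <- x[tri[, 3L], , drop = FALSE]
  signed <- sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
                a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
                a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
  # base cap: fan from the base-ring centroid
  base <- x[seq_len(points_per_ring), , drop = FALSE]
  c0 <- colMeans(base)
  nxt <- c(seq_len(points_per_ring)[-1L], 1L)
  # wound as (centroid, next, current) to match the band orientation
  a <- base[nxt, , drop = FALSE]; b <- base
  signed <- signed + sum(
    c0[1L] * (a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]) -
    c0[2L] * (a[, 1L] * b[, 3L] - a[, 3L] * b[, 1L]) +
    c0[3L] * (a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])) / 6
  abs(signed) / 1000
}

#' Volume curve of a homologous series
#'
#' @param series a `homologous_series` whose shapes carry (or are given)
#'   the ring/apex topology.
#' @param rings,points_per_ring topology override.
#' @return list of class `volume_curve`: `volumes` (ml, length 12),
#'   `times` (ms).
#' @export
volume_curve <- function(series, rings = NULL, points_per_ring = NULL) {
  v <- vapply(series$shapes, mesh_volume, 0, rings = rings,
              points_per_ring = points_per_ring)
  structure(list(volumes = v, times = series$homologous_times),
            class = "volume_curve")
}

#' Phasic LA function indicators from a 12-point volume curve
#'
#' Standard phasic (Hoit-style) decomposition of LA function. With
#' \eqn{V_{max}} at LA end-diastole (grid position 5), \eqn{V_{min}} the
#' curve minimum and \eqn{V_{preA}} the pre-atrial-contraction volume at
#' the P peak (position 9):
#' \itemize{
#'   \item global (total emptying) EF = 100 (Vmax - Vmin) / Vmax
#'   \item reservoir (expansion index) = 100 (Vmax - Vmin) / Vmin
#'   \item conduit (passive) EF = 100 (Vmax - VpreA) / Vmax
#'   \item booster (active) EF = 100 (VpreA - Vmin) / VpreA
#'   \item booster absolute = VpreA - Vmin (ml)
#' }
#' Vmax is read at the end-diastolic event; when the curve maximum exceeds
#' it by 5\% or more the maximum is used instead, with a warning.
#'
#' @param curve a `volume_curve` (or numeric vector of 12 volumes).
#' @param ed_position,p_position 1-based grid positions of LA end-diastole
#'   and the P peak.
#' @return named list of class `la_indicators` with fields `v_max`,
#'   `v_min`, `v_preA`, `ef_global`, `ef_reservoir`, `ef_conduit`,
#'   `ef_booster`, `booster_abs`, `flagged`.
#' @export
la_function_indicators <- function(curve, ed_position = 5L, p_position = 9L) {
  v <- if (inherits(curve, "volume_curve")) curve$volumes else as.numeric(curve)
  if (length(v) != 12L) stop("expected a 12-point volume curve")
  if (any(v <= 0)) stop("volumes must be positive")
  v_max <- v[ed_position]
  if (max(v) >= v_max * 1.05) {
    warning("curve maximum exceeds the end-diastolic volume by >= 5%; using the maximum")
    v_max <- max(v)
  }
  v_min <- min(v)
  v_preA <- v[p_position]
  flagged <- FALSE
  if (v_preA > v_max + 1e-9 || v_preA < v_min - 1e-9) {
    flagged <- TRUE
    warning("pre-A volume outside [v_min, v_max]; indicators flagged")
  }
  structure(list(
    v_max = v_max, v_min = v_min, v_preA = v_preA,
    ef_global = 100 * (v_max - v_min) / v_max,
    ef_reservoir = 100 * (v_max - v_min) / v_min,
    ef_conduit = 100 * (v_max - v_preA) / v_max,
    ef_booster = 100 * (v_preA - v_min) / v_preA,
    booster_abs = v_preA - v_min,
    flagged = flagged), class = "la_indicators")
}

#' Surrogate classic 3DSTE global parameters
#'
#' The conventional speckle-tracking deformation outputs, rebuilt from the
#' landmark cloud as the comparison baseline for the deformation analysis:
#' at each homologous time, global longitudinal strain (mean per-meridian
#' polyline length change, base to apex, vs the end-systolic frame, %),
#' global circumferential strain (mean per-ring perimeter change vs
#' end-systole, %) and cavity volume. End-systole is the minimum-volume
#' frame of the series — in the classic convention it is the undeformed
#' reference, so both strains are 0 there.
#'
#' @param series a `homologous_series` with ring/apex topology.
#' @param rings,points_per_ring topology override.
#' @return data frame: time_index, time_ms, gls, gcs, volume_ml.
#' @export
classic_global_parameters <- function(series, rings = NULL,
                                      points_per_ring = NULL) {
  topo <- config_topology(series$shapes[[1L]])
  rings <- rings %||% topo$rings
  points_per_ring <- points_per_ring %||% topo$points_per_ring
  if (is.null(rings)) stop("classic parameters need the ring/apex topology")
  P <- points_per_ring
  apex_row <- rings * P + 1L

  meridian_lengths <- function(x) {
    # one polyline per angular position: ring 1 ... ring R, then the apex
    vapply(seq_len(P), function(p) {
      rows <- (seq_len(rings) - 1L) * P + p
      pts <- rbind(x[rows, , drop = FALSE], x[apex_row, ])
      sum(sqrt(rowSums(diff(pts)^2)))
    }, 0)
  }
  ring_perimeters <- function(x) {
    vapply(seq_len(rings), function(r) {
      rows <- (r - 1L) * P + seq_len(P)
      pts <- x[rows, , drop = FALSE]
      sum(sqrt(rowSums((pts[c(seq_len(P)[-1L], 1L), ] - pts)^2)))
    }, 0)
  }

  vols <- vapply(series$shapes, mesh_volume, 0, rings = rings,
                 points_per_ring = P)
  es <- which.min(vols)
  ml_es <- meridian_lengths(as.matrix(series$shapes[[es]]))
  rp_es <- ring_perimeters(as.matrix(series$shapes[[es]]))
  gls <- vapply(series$shapes, function(s)
    mean(100 * (meridian_lengths(as.matrix(s)) - ml_es) / ml_es), 0)
  gcs <- vapply(series$shapes, function(s)
    mean(100 * (ring_perimeters(as.matrix(s)) - rp_es) / rp_es), 0)
  data.frame(time_index = seq_along(vols),
             time_ms = series$homologous_times,
             gls = gls, gcs = gcs, volume_ml = vols)
}
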