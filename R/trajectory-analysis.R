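#' Build a deformation trajectory for one subject
#'
#' Treats the subject's deformation PC scores at the 12 homologous times as
#' a 12-landmark configuration in q dimensions: the "shape of the motion".
#' These trajectory landmarks are themselves homologous across subjects
#' thanks to the homologous-time interpolation.
#'
#' @param scores 12 x c matrix of deformation PC scores for one subject
#'   (rows ordered by homologous time), or a `deformation_pca` plus
#'   `subject_id`.
#' @param q number of leading PCs used as trajectory dimensions (default 3;
#'   any q >= 2 up to the available components is accepted).
#' @param subject_id,group metadata attached to the trajectory.
#' @return list of class `trajectory`: `points` (12 x q), `subject_id`,
#'   `group`.
#' @export
build_trajectory <- function(scores, q = 3L, subject_id = NA_character_,
                             group = "unknown") {
  if (inherits(scores, "deformation_pca")) {
    dpca <- scores
    sel <- dpca$index$subject_id == subject_id
    if (!any(sel)) stop("unknown subject: ", subject_id)
    group <- dpca$index$group[sel][1L]
    ord <- order(dpca$index$time_index[sel])
    scores <- dpca$pca$scores[sel, , drop = FALSE][ord, , drop = FALSE]
  }
  scores <- as.matrix(scores)
  if (nrow(scores) != 12L)
    stop("incomplete trajectory: need scores at all 12 homologous times")
  if (q < 2L) stop("q must be at least 2")
  if (q > ncol(scores))
    stop("incomplete trajectory: only ", ncol(scores), " components available")
  structure(list(points = scores[, seq_len(q), drop = FALSE],
                 subject_id = subject_id, group = group),
            class = "trajectory")
}

#' Trajectories for all subjects of a deformation PCA
#'
#' @param dpca a `deformation_pca`.
#' @param q trajectory dimension, see [build_trajectory()].
#' @return named list of `trajectory` objects.
#' @export
cohort_trajectories <- function(dpca, q = 3L) {
  ids <- unique(dpca$index$subject_id)
  out <- lapply(ids, function(id) build_trajectory(dpca, q = q,
                                                   subject_id = id))
  names(out) <- ids
  out
}

#' Anchor-only GPA of trajectory configurations (shape space)
#'
#' Second-order GPA: each 12-landmark trajectory is superimposed in shape
#' space, but translation, scale and rotation are estimated from the anchor
#' landmarks only — by default landmarks 1, 5, 9, the strictly homologous
#' events (R peak, LA end-diastole, P peak). The interpolated landmarks are
#' passively carried along by the fitted transform, so imprecision in the
#' interpolated times cannot distort the alignment. Scale is the centroid
#' size of the anchor sub-configuration; reflections are excluded.
#'
#' @param trajectories list of `trajectory` objects with identical q.
#' @param anchors 1-based landmark indices used to estimate the transforms
#'   (at least 3 for q >= 3).
#' @param tol,max_iter GPA convergence controls, see [gpa()].
#' @return list of class `trajectory_gpa`: `aligned` (list of 12 x q
#'   matrices), `mean_trajectory`, `anchors`, `subject_id`, `group`,
#'   `iterations`.
#' @export
trajectory_gpa <- function(trajectories, anchors = c(1L, 5L, 9L),
                           tol = 1e-10, max_iter = 200L) {
  qs <- vapply(trajectories, function(tr) ncol(tr$points), 0L)
  if (length(unique(qs)) != 1L)
    stop("shape mismatch: trajectories have different q")
  q <- qs[1L]
  anchors <- as.integer(anchors)
  if (any(anchors < 1L | anchors > 12L)) stop("anchors out of range")
  if (q >= 3L && length(anchors) < 3L)
    stop("under-determined alignment: need at least 3 anchors for q >= 3")

  n <- length(trajectories)
  pts <- lapply(trajectories, function(tr) as.matrix(tr$points))
  # translate by anchor centroid, scale by anchor centroid size
  ctr <- lapply(pts, function(p) colMeans(p[anchors, , drop = FALSE]))
  pts <- Map(function(p, c0) sweep(p, 2L, c0), pts, ctr)
  cs <- vapply(pts, function(p) sqrt(sum(p[anchors, , drop = FALSE]^2)), 0)
  if (any(cs == 0)) stop("degenerate configuration: coincident anchors")
  pts <- Map(`/`, pts, cs)

  # GPA loop on the anchor sub-configurations; rotations applied to all 12
  anchor_cfg <- lapply(pts, function(p) p[anchors, , drop = FALSE])
  gm <- Reduce(`+`, anchor_cfg) / n
  rot <- rep(list(diag(q)), n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) rot[[i]] <- optimal_rotation(anchor_cfg[[i]], gm)
    rotated <- Map(`%*%`, anchor_cfg, rot)
    gm_new <- Reduce(`+`, rotated) / n
    change <- sqrt(sum((gm_new - gm)^2))
    gm <- gm_new
    if (change < tol || iter >= max_iter) break
  }
  aligned <- Map(`%*%`, pts, rot)
  structure(list(aligned = aligned,
                 mean_trajectory = Reduce(`+`, aligned) / n,
                 anchors = anchors,
                 subject_id = vapply(trajectories, `[[`, "", "subject_id"),
                 group = vapply(trajectories, `[[`, "", "group"),
                 iterations = iter),
            class = "trajectory_gpa")
}

#' PCA of aligned trajectory shapes
#'
#' PCA over the vectorized anchor-aligned trajectories. The resulting PC
#' axes are trajectory-morphology modes — e.g. a bend of the path around
#' specific homologous times — not LA shape modes.
#'
#' @param tgpa a `trajectory_gpa`.
#' @param n_components components to retain (default: all).
#' @return a `shape_pca` with attributes `subject_id` and `group` aligned to
#'   its score rows.
#' @export
trajectory_shape_pca <- function(tgpa, n_components = NULL) {
  pca <- shape_pca(tgpa$aligned, n_components = n_components)
  attr(pca, "subject_id") <- tgpa$subject_id
  attr(pca, "group") <- tgpa$group
  pca
}

#' Trajectory centroid size
#'
#' Centroid size of the raw (pre-scaling) 12 x q trajectory configuration:
#' the overall magnitude of the subject's deformation excursion across the
#' cycle.
#'
#' @param trajectory a `trajectory` (or a 12 x q matrix).
#' @return positive scalar.
#' @export
trajectory_size <- function(trajectory) {
  p <- if (inherits(trajectory, "trajectory")) trajectory$points
       else as.matrix(trajectory)
  centroid_size(p)
}

#' Trajectory orientation angles
#'
#' Direction of the vector from trajectory landmark 1 (R peak) to landmark
#' 5 (LA end-diastole), projected on the PC1/PC2 and PC1/PC3 planes of the
#' deformation space; two-argument arctangent, degrees in (-180, 180].
#'
#' @param trajectory a `trajectory` (or 12 x q matrix, q >= 3).
#' @return named numeric vector `c(angle_12, angle_13)` (degrees).
#' @export
trajectory_orientation <- function(trajectory) {
  p <- if (inherits(trajectory, "trajectory")) trajectory$points
       else as.matrix(trajectory)
  if (ncol(p) < 3L) stop("orientation needs q >= 3")
  v <- p[5L, ] - p[1L, ]
  if (sqrt(sum(v^2)) == 0)
    stop("undefined orientation: landmarks 1 and 5 coincide")
  c(angle_12 = atan2(v[2L], v[1L]) * 180 / pi,
    angle_13 = atan2(v[3L], v[1L]) * 180 / pi)
}

#' Trajectory attributes for a cohort
#'
#' Anchor-only GPA + PCA of the trajectory shapes, plus per-subject size
#' and orientation angles.
#'
#' @param trajectories list of `trajectory` objects.
#' @param anchors anchor landmarks, see [trajectory_gpa()].
#' @param n_components trajectory-shape PCs to keep in the output table.
#' @return list of class `trajectory_attributes`: `table` (data frame with
#'   subject_id, group, shape_pc1..., size, angle_12, angle_13), `pca`,
#'   `gpa`.
#' @export
trajectory_attributes <- function(trajectories, anchors = c(1L, 5L, 9L),
                                  n_components = 10L) {
  tgpa <- trajectory_gpa(trajectories, anchors = anchors)
  pca <- trajectory_shape_pca(tgpa)
  nc <- min(n_components, ncol(pca$scores))
  tab <- data.frame(subject_id = tgpa$subject_id, group = tgpa$group,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nc)) tab[[paste0("shape_pc", j)]] <- pca$scores[, j]
  tab$size <- vapply(trajectories, trajectory_size, 0)
  ang <- t(vapply(trajectories, trajectory_orientation, numeric(2L)))
  tab$angle_12 <- ang[, 1L]
  tab$angle_13 <- ang[, 2L]
  structure(list(table = tab, pca = pca, gpa = tgpa),
            class = "trajectory_attributes")
}
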