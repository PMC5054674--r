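#' Electromechanical event annotations
#'
#' The three strictly homologous times of one cardiac cycle — R peak, LA
#' end-diastolic (maximum) volume, P peak — plus the next R peak closing the
#' cycle. Times in ms, strictly increasing.
#'
#' @param t_R,t_ED,t_P,t_R_next event times (ms).
#' @return list of class `event_annotations`.
#' @export
event_annotations <- function(t_R, t_ED, t_P, t_R_next) {
  ev <- list(t_R = t_R, t_ED = t_ED, t_P = t_P, t_R_next = t_R_next)
  if (any(!is.finite(unlist(ev))))
    stop("invalid events: non-finite time")
  if (!(t_R < t_ED && t_ED < t_P && t_P < t_R_next))
    stop("invalid events: require t_R < t_ED < t_P < t_R_next")
  structure(ev, class = "event_annotations")
}

#' Cine sequence for one subject
#'
#' An ordered series of landmark configurations with per-frame acquisition
#' times and the annotated electromechanical events of (at least) the first
#' cycle.
#'
#' @param frames list of landmark matrices (identical k x m).
#' @param times frame times (ms), strictly increasing, spanning at least
#'   `[t_R, t_R_next]`.
#' @param events an [event_annotations()].
#' @param subject_id character id.
#' @param group `"Control"`, `"HCM"` or `"unknown"`.
#' @return list of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, times, events, subject_id,
                          group = "unknown") {
  if (length(frames) != length(times))
    stop("frames and times must have equal length")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (min(times) > events$t_R || max(times) < events$t_R_next)
    stop("frames must span the annotated cycle [t_R, t_R_next]")
  structure(list(frames = frames, times = times, events = events,
                 subject_id = subject_id, group = group),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  cat(sprintf("Cine '%s' (%s): %d frames of %d landmarks, %.0f-%.0f ms\n",
              x$subject_id, x$group, length(x$frames), nrow(x$frames[[1L]]),
              min(x$times), max(x$times)))
  invisible(x)
}

#' The 12-point homologous time grid
#'
#' The three strictly homologous events split the cycle into the reservoir,
#' conduit and booster-pump phases; within each phase 3 equally spaced
#' interior times are added. The next R peak is the first point of the next
#' cycle and is excluded, giving 12 times with the strict events at
#' positions 1, 5 and 9 (1-based).
#'
#' @param events an [event_annotations()].
#' @return strictly increasing numeric vector of length 12 (ms).
#' @export
homologous_time_grid <- function(events) {
  if (!inherits(events, "event_annotations"))
    events <- do.call(event_annotations, as.list(events))
  seg <- function(a, b) a + (b - a) * (0:3) / 4
  grid <- c(seg(events$t_R, events$t_ED),
            seg(events$t_ED, events$t_P),
            seg(events$t_P, events$t_R_next))
  stopifnot(length(grid) == 12L, all(diff(grid) > 0))
  grid
}

#' Pooled GPA + PCA over all observed frames of a cohort
#'
#' Runs one Generalized Procrustes Analysis in size-and-shape space over the
#' pooled frames of every subject, followed by PCA of the aligned
#' configurations. A single pooled alignment puts all subjects in a common
#' coordinate frame, which the later linear-shift step relies on; per-frame
#' scores are retrievable by subject and time.
#'
#' @param cohort list of [cine_sequence()] objects with identical landmark
#'   counts.
#' @param space Procrustes space; the LA pipeline uses `"SSS"` so that size
#'   is retained as a functional attribute.
#' @param ... passed to [gpa()].
#' @return list of class `pooled_decomposition`: `gpa` (the pooled
#'   `gpa_fit`), `pca` (a `shape_pca` over all frames), `index` (data frame
#'   with subject_id, group, frame, time_ms per score row), `cohort_events`
#'   (per-subject event annotations), `k`, `m`.
#' @export
pooled_observed_decomposition <- function(cohort, space = "SSS", ...) {
  if (length(cohort) < 2L) stop("need at least 2 subjects")
  ks <- vapply(cohort, function(s) nrow(s$frames[[1L]]), 0L)
  if (length(unique(ks)) != 1L)
    stop("shape mismatch: subjects have different landmark counts")
  frames <- unlist(lapply(cohort, `[[`, "frames"), recursive = FALSE)
  index <- do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               frame = seq_along(s$times), time_ms = s$times,
               stringsAsFactors = FALSE)))
  fit <- gpa(frames, space = space, ...)
  pca <- shape_pca(fit)
  events <- setNames(lapply(cohort, `[[`, "events"),
                     vapply(cohort, `[[`, "", "subject_id"))
  structure(list(gpa = fit, pca = pca, index = index,
                 cohort_events = events,
                 topology = config_topology(cohort[[1L]]$frames[[1L]]),
                 k = nrow(fit$grand_mean), m = ncol(fit$grand_mean)),
            class = "pooled_decomposition")
}

#' Retrieve one subject's per-frame PC scores
#'
#' @param decomp a `pooled_decomposition`.
#' @param subject_id subject to extract.
#' @return list with `times` (ms) and `scores` (frames x components).
#' @export
subject_scores <- function(decomp, subject_id) {
  sel <- decomp$index$subject_id == subject_id
  if (!any(sel)) stop("unknown subject: ", subject_id)
  list(times = decomp$index$time_ms[sel],
       scores = decomp$pca$scores[sel, , drop = FALSE])
}

#' Interpolate PC score traces at query times
#'
#' Componentwise interpolation of a score matrix sampled at observed frame
#' times. The default natural cubic spline reproduces observed values
#' exactly and is smooth across the cycle; linear interpolation is
#' available. Because both interpolants are linear in the data, the
#' interpolation is applied as a single query x frame weight matrix, which
#' keeps full-rank score sets cheap.
#'
#' @param times observed times (ms), strictly increasing.
#' @param score_matrix frames x components matrix.
#' @param query_times times to evaluate, all within `[min(times), max(times)]`.
#' @param method `"spline"` (natural cubic) or `"linear"`.
#' @return `length(query_times)` x components matrix.
#' @export
interpolate_scores <- function(times, score_matrix, query_times,
                               method = c("spline", "linear")) {
  method <- match.arg(method)
  score_matrix <- as.matrix(score_matrix)
  if (length(times) != nrow(score_matrix))
    stop("times and score rows differ")
  if (any(query_times < min(times) - 1e-9) ||
      any(query_times > max(times) + 1e-9))
    stop("out of range: extrapolation is not supported")
  w <- interp_weights(times, query_times, method)
  w %*% score_matrix
}

# Weight matrix W (n_query x n_times) with interp(y) = W %*% y, built by
# passing unit vectors through the chosen interpolant.
interp_weights <- function(times, query_times, method) {
  n <- length(times)
  w <- matrix(0, length(query_times), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    w[, j] <- if (method == "spline")
      splinefun(times, e, method = "natural")(query_times)
    else
      approx(times, e, xout = query_times)$y
  }
  w
}

#' Homologous-time shape series for one subject
#'
#' Interpolates the subject's pooled PC scores at the 12 homologous times of
#' its own event annotations and rebuilds the configurations from the
#' retained loadings and the pooled consensus — giving every subject a
#' comparable series of 12 shapes regardless of its native frame rate.
#'
#' @param decomp a `pooled_decomposition`.
#' @param subject_id subject to reconstruct.
#' @param method interpolation method, see [interpolate_scores()].
#' @return list of class `homologous_series`: `shapes` (12 k x m matrices in
#'   the pooled aligned frame), `homologous_times`, `scores` (12 x
#'   components), `subject_id`, `group`.
#' @export
reconstruct_homologous_series <- function(decomp, subject_id,
                                          method = "spline") {
  ev <- decomp$cohort_events[[subject_id]]
  if (is.null(ev)) stop("invalid events: no annotations for ", subject_id)
  grid <- homologous_time_grid(ev)
  ss <- subject_scores(decomp, subject_id)
  sc <- interpolate_scores(ss$times, ss$scores, grid, method = method)
  shapes <- pca_reconstruct(decomp$pca, sc)
  if (!is.list(shapes)) shapes <- list(shapes)
  topo <- decomp$topology
  if (!is.null(topo$rings))
    shapes <- lapply(shapes, landmark_config, rings = topo$rings,
                     points_per_ring = topo$points_per_ring,
                     apex_index = topo$apex_index)
  group <- decomp$index$group[match(subject_id, decomp$index$subject_id)]
  structure(list(shapes = shapes, homologous_times = grid, scores = sc,
                 subject_id = subject_id, group = group),
            class = "homologous_series")
}

#' Homologous series for a whole cohort
#'
#' Convenience wrapper: [pooled_observed_decomposition()] followed by
#' [reconstruct_homologous_series()] for every subject.
#'
#' @param cohort list of [cine_sequence()].
#' @param method interpolation method.
#' @param ... passed to [pooled_observed_decomposition()].
#' @return list with `series` (one `homologous_series` per subject) and
#'   `decomposition`.
#' @export
homologize_cohort <- function(cohort, method = "spline", ...) {
  decomp <- pooled_observed_decomposition(cohort, ...)
  ids <- vapply(cohort, `[[`, "", "subject_id")
  series <- lapply(ids, function(id)
    reconstruct_homologous_series(decomp, id, method = method))
  names(series) <- ids
  list(series = series, decomposition = decomp)
}
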