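#' Linear-shift transport of a subject's deformations onto the grand mean
#'
#' The linear shift (LS) is the tangent-plane approximation of parallel
#' transport: because size-and-shape space aligned configurations already
#' lie in the Euclidean tangent space at the grand mean (GM), a subject's
#' within-cycle deformations can be detached from its own mean shape and
#' re-attached to the GM by simple vector addition,
#' \code{GM + (shape_t - subject_reference)}. This removes inter-individual
#' shape differences, leaving pure deformation: both end-systole and
#' end-diastole become deformed states of the common mannequin.
#'
#' @param series a `homologous_series` (shapes in the pooled aligned frame).
#' @param grand_mean k x m matrix, the GM of the cohort's homologous shapes.
#' @param reference `"mean"` (default; the subject's mean over its 12
#'   homologous shapes, so each transported trajectory has mean exactly GM)
#'   or `"first_frame"` (deformations relative to the R-peak shape).
#' @return list of class `transported_series`: `shapes` (12 k x m
#'   matrices), `homologous_times`, `subject_id`, `group`, `reference`.
#' @export
linear_shift <- function(series, grand_mean, reference = c("mean", "first_frame")) {
  reference <- match.arg(reference)
  gm <- as.matrix(grand_mean)
  k <- nrow(series$shapes[[1L]])
  if (nrow(gm) != k || ncol(gm) != ncol(series$shapes[[1L]]))
    stop("shape mismatch: grand mean dimensions differ from series shapes")
  ref <- if (reference == "mean")
    Reduce(`+`, series$shapes) / length(series$shapes)
  else
    series$shapes[[1L]]
  shapes <- lapply(series$shapes, function(s) gm + (as.matrix(s) - ref))
  structure(list(shapes = shapes,
                 homologous_times = series$homologous_times,
                 subject_id = series$subject_id, group = series$group,
                 reference = reference),
            class = "transported_series")
}

#' Deformation PCA of linear-shift transported shapes
#'
#' Pools every subject's 12 transported shapes (n_obs = 12 x n_subjects)
#' and decomposes them about the grand mean. The resulting PC scores
#' describe pure deformation: nearby points are subjects undergoing the
#' same deformation, not subjects with the same shape.
#'
#' @param transported list of `transported_series` (one per subject).
#' @param grand_mean the GM used for the shift (k x m matrix).
#' @param n_components components to retain (default: all).
#' @return list of class `deformation_pca`: `pca` (a `shape_pca` centered on
#'   the GM), `index` (data frame subject_id, group, time_index,
#'   time_ms per score row), `grand_mean`, `k`, `m`.
#' @export
deformation_pca <- function(transported, grand_mean, n_components = NULL) {
  if (length(transported) < 2L) stop("need at least 2 subjects")
  gm <- as.matrix(grand_mean)
  shapes <- unlist(lapply(transported, `[[`, "shapes"), recursive = FALSE)
  index <- do.call(rbind, lapply(transported, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               time_index = seq_along(s$shapes),
               time_ms = s$homologous_times, stringsAsFactors = FALSE)))
  pca <- shape_pca(shapes, center_on = as.vector(gm),
                   n_components = n_components)
  structure(list(pca = pca, index = index, grand_mean = gm,
                 k = nrow(gm), m = ncol(gm)),
            class = "deformation_pca")
}

#' @export
print.deformation_pca <- function(x, ...) {
  cat(sprintf("Deformation PCA: %d subjects x %d times, %d components\n",
              length(unique(x$index$subject_id)), max(x$index$time_index),
              length(x$pca$eigenvalues)))
  invisible(x)
}

#' Deformation scores as a subject x time x component array
#'
#' @param dpca a `deformation_pca`.
#' @param n_components leading components to keep (default: all).
#' @return numeric array n_subjects x 12 x n_components with subject
#'   dimnames; attribute `groups` carries the per-subject group labels.
#' @export
deformation_score_array <- function(dpca, n_components = NULL) {
  ids <- unique(dpca$index$subject_id)
  nt <- max(dpca$index$time_index)
  nc <- if (is.null(n_components)) ncol(dpca$pca$scores)
        else min(n_components, ncol(dpca$pca$scores))
  arr <- array(NA_real_, c(length(ids), nt, nc),
               dimnames = list(ids, NULL, NULL))
  for (i in seq_along(ids)) {
    sel <- dpca$index$subject_id == ids[i]
    arr[i, dpca$index$time_index[sel], ] <-
      dpca$pca$scores[sel, seq_len(nc), drop = FALSE]
  }
  attr(arr, "groups") <- dpca$index$group[match(ids, dpca$index$subject_id)]
  arr
}

#' Rebuild a deformed shape from deformation PC scores
#'
#' `GM + sum_i score_i * loading_i`, reshaped to k x m, together with the
#' per-landmark displacement magnitude field |x_M - x| (distance of each
#' landmark from its grand-mean position) used for surface colormaps.
#'
#' @param dpca a `deformation_pca`.
#' @param scores numeric vector of leading PC scores (length <= number of
#'   components).
#' @return list: `shape` (k x m matrix), `displacement` (length-k vector of
#'   per-landmark distances from the GM, mm).
#' @export
deformed_shape_at <- function(dpca, scores) {
  shape <- pca_reconstruct(dpca$pca, scores)
  disp <- sqrt(rowSums((shape - dpca$grand_mean)^2))
  list(shape = shape, displacement = disp)
}

#' Run the full deformation analysis on a cohort of homologous series
#'
#' GPA in SSS + LS in SSS + PCA: computes the grand mean of all subjects'
#' homologous shapes, linear-shifts every subject onto it, and runs the
#' deformation PCA.
#'
#' @param series list of `homologous_series` (from [homologize_cohort()]).
#' @param reference shift reference, see [linear_shift()].
#' @param n_components components to retain in the PCA.
#' @return a `deformation_pca`; the transported series are attached as
#'   attribute `transported`.
#' @export
deformation_analysis <- function(series, reference = "mean",
                                 n_components = NULL) {
  all_shapes <- unlist(lapply(series, `[[`, "shapes"), recursive = FALSE)
  gm <- Reduce(`+`, all_shapes) / length(all_shapes)
  transported <- lapply(series, linear_shift, grand_mean = gm,
                        reference = reference)
  dpca <- deformation_pca(transported, gm)
  attr(dpca, "transported") <- transported
  dpca
}
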