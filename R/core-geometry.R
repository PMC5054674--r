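#' Landmark configuration
#'
#' A single landmark cloud: a \code{k x m} numeric matrix of coordinates in
#' mm (rows are landmarks), optionally carrying the LA ring/apex topology as
#' attributes. The endocardial sampling used throughout is \code{rings}
#' horizontal circles of \code{points_per_ring} landmarks each, ordered
#' base to apex, followed by the apex point, so
#' \code{k = rings * points_per_ring + 1}.
#'
#' @param coords numeric matrix, k landmarks by m dimensions (m = 3 for LA
#'   data), all entries finite.
#' @param rings,points_per_ring integer topology, or `NULL` for a plain
#'   cloud with no surface topology.
#' @param apex_index 0-based index of the apex landmark (defaults to the
#'   last row when a topology is given); 0-based to match the on-disk
#'   format.
#' @return the coordinate matrix with class `landmark_config` and topology
#'   attributes.
#' @export
landmark_config <- function(coords, rings = NULL, points_per_ring = NULL,
                            apex_index = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || !all(is.finite(coords)))
    stop("invalid input: landmark coordinates must be finite numbers")
  if (!is.null(rings)) {
    if (is.null(points_per_ring))
      stop("points_per_ring required when rings is given")
    k_expect <- rings * points_per_ring + 1L
    if (nrow(coords) != k_expect)
      stop(sprintf("topology mismatch: expected %d landmarks (%d x %d + apex), got %d",
                   k_expect, rings, points_per_ring, nrow(coords)))
    if (is.null(apex_index)) apex_index <- nrow(coords) - 1L
    attr(coords, "rings") <- as.integer(rings)
    attr(coords, "points_per_ring") <- as.integer(points_per_ring)
    attr(coords, "apex_index") <- as.integer(apex_index)
  }
  class(coords) <- c("landmark_config", "matrix", "array")
  coords
}

config_topology <- function(config) {
  list(rings = attr(config, "rings"),
       points_per_ring = attr(config, "points_per_ring"),
       apex_index = attr(config, "apex_index"))
}

as_coord_matrix <- function(config) {
  x <- unclass(config)
  attr(x, "rings") <- NULL
  attr(x, "points_per_ring") <- NULL
  attr(x, "apex_index") <- NULL
  x
}

#' Center a configuration on its centroid
#'
#' Translates the landmark cloud so its centroid (column mean) is the
#' origin; shape, size and orientation are untouched.
#'
#' @param config landmark matrix (k x m).
#' @return centered configuration of the same class/attributes.
#' @export
center <- function(config) {
  x <- as.matrix(config)
  if (!all(is.finite(x))) stop("invalid input: non-finite coordinates")
  out <- sweep(x, 2L, colMeans(x))
  attributes(out) <- attributes(config)
  out
}

#' Centroid size
#'
#' The standard morphometric size measure: the square root of the summed
#' squared distances of all landmarks from their centroid. Invariant under
#' rotation and translation; scales linearly under uniform scaling.
#'
#' @param config landmark matrix (k x m), k >= 2.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  x <- as.matrix(config)
  if (nrow(x) < 2L) stop("degenerate configuration: need at least 2 landmarks")
  xc <- sweep(x, 2L, colMeans(x))
  cs <- sqrt(sum(xc^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  cs
}

#' Optimal rotation between two centered configurations
#'
#' Solves the orthogonal Procrustes problem: the proper rotation R (det +1,
#' reflections excluded — anatomical landmarks must not mirror) minimizing
#' \code{||moving \%*\% R - target||_F}. Kabsch solution via SVD of the
#' cross-covariance.
#'
#' @param moving,target centered k x m matrices with equal dimensions.
#' @return m x m rotation matrix with determinant +1.
#' @export
optimal_rotation <- function(moving, target) {
  a <- as.matrix(moving); b <- as.matrix(target)
  if (!all(dim(a) == dim(b)))
    stop("shape mismatch: configurations must have identical dimensions")
  h <- crossprod(a, b)                     # m x m
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  m <- ncol(a)
  sv$u %*% diag(c(rep(1, m - 1L), d), m) %*% t(sv$v)
}

#' Generalized Procrustes Analysis in shape or size-and-shape space
#'
#' Iteratively superimposes configurations on their evolving mean by
#' translation and proper rotation. In shape space (`space = "SS"`) each
#' configuration is additionally scaled to unit centroid size; in
#' size-and-shape space (`space = "SSS"`, the default) sizes are retained,
#' so after alignment the configurations lie directly in the Euclidean
#' tangent space at the grand mean and PCA can be applied without further
#' projection.
#'
#' @param configs list of k x m matrices (identical k, m), or a k x m x n
#'   array.
#' @param space `"SSS"` (no scaling) or `"SS"` (unit centroid size).
#' @param tol convergence tolerance on the Frobenius change of the mean.
#' @param max_iter iteration cap; non-convergence raises a warning and sets
#'   `converged = FALSE` on the result.
#' @return object of class `gpa_fit`: `aligned` (list of k x m matrices),
#'   `grand_mean`, `rotations`, `scales` (all 1 in SSS mode), `space`,
#'   `iterations`, `final_change`, `converged`, `objective` (per-iteration
#'   sum of squared distances to the mean).
#' @export
gpa <- function(configs, space = c("SSS", "SS"), tol = 1e-10, max_iter = 200L) {
  space <- match.arg(space)
  if (is.array(configs) && length(dim(configs)) == 3L)
    configs <- lapply(seq_len(dim(configs)[3]), function(i) configs[, , i])
  n <- length(configs)
  if (n < 2L) stop("need at least 2 configurations")
  k <- nrow(configs[[1L]]); m <- ncol(configs[[1L]])
  for (x in configs)
    if (nrow(x) != k || ncol(x) != m)
      stop("shape mismatch: all configurations must share dimensions")

  centered <- lapply(configs, function(x) {
    x <- as.matrix(x)
    sweep(x, 2L, colMeans(x))
  })
  sizes <- vapply(centered, function(x) sqrt(sum(x^2)), 0)
  if (any(sizes == 0)) stop("degenerate configuration: zero centroid size")
  scales <- rep(1, n)
  if (space == "SS") {
    scales <- 1 / sizes
    centered <- Map(function(x, s) x * s, centered, scales)
  }

  aligned <- centered
  rotations <- rep(list(diag(m)), n)
  gm <- Reduce(`+`, aligned) / n
  objective <- numeric(0)
  change <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      r <- optimal_rotation(centered[[i]], gm)
      rotations[[i]] <- r
      aligned[[i]] <- centered[[i]] %*% r
    }
    gm_new <- Reduce(`+`, aligned) / n
    objective <- c(objective,
                   sum(vapply(aligned, function(x) sum((x - gm_new)^2), 0)))
    change <- sqrt(sum((gm_new - gm)^2))
    gm <- gm_new
    if (change < tol) break
  }
  converged <- change < tol
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations (change %.3e)",
                    max_iter, change))

  structure(list(aligned = aligned, grand_mean = gm, rotations = rotations,
                 scales = scales, space = space, iterations = iter,
                 final_change = change, converged = converged,
                 objective = objective),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("GPA (%s): %d configurations of %d x %d, %d iterations (change %.2e)\n",
              x$space, length(x$aligned), nrow(x$grand_mean),
              ncol(x$grand_mean), x$iterations, x$final_change))
  invisible(x)
}

# Vectorize a list of k x m matrices into an n x (k*m) data matrix
# (column-major: all x, then all y, then all z).
vectorize_configs <- function(configs) {
  do.call(rbind, lapply(configs, as.vector))
}

devectorize_config <- function(v, k, m = 3L) {
  matrix(v, nrow = k, ncol = m)
}

#' Principal component analysis of aligned configurations
#'
#' PCA of the vectorized aligned landmark configurations, computed by SVD of
#' the centered data matrix. Centering is about the sample mean by default,
#' or about an externally supplied vector (used by the deformation analysis
#' to decompose about the grand mean). Component signs follow a
#' deterministic convention: the largest-magnitude loading entry of each
#' component is positive.
#'
#' @param x a `gpa_fit`, a list of k x m matrices, or an n x p data matrix
#'   of already-vectorized configurations.
#' @param center_on `"mean"` or a numeric vector of length p.
#' @param n_components number of components to retain (default: all).
#' @return object of class `shape_pca`: `mean_vector` (the centering
#'   vector), `eigenvalues`, `loadings` (p x c, orthonormal columns),
#'   `scores` (n x c), `variance_fraction`, `cumulative_fraction`, `k`, `m`.
#' @export
shape_pca <- function(x, center_on = "mean", n_components = NULL) {
  if (inherits(x, "gpa_fit")) {
    k <- nrow(x$grand_mean); m <- ncol(x$grand_mean)
    dat <- vectorize_configs(x$aligned)
  } else if (is.list(x)) {
    k <- nrow(x[[1L]]); m <- ncol(x[[1L]])
    dat <- vectorize_configs(x)
  } else {
    dat <- as.matrix(x)
    k <- ncol(dat); m <- 1L
  }
  n <- nrow(dat)
  if (n < 2L) stop("insufficient data: need at least 2 observations")
  if (identical(center_on, "mean")) {
    mu <- colMeans(dat)
  } else {
    mu <- as.numeric(center_on)
    if (length(mu) != ncol(dat))
      stop("shape mismatch: external center has wrong length")
  }
  xc <- sweep(dat, 2L, mu)
  rank_max <- min(n, ncol(dat))
  nc <- if (is.null(n_components)) rank_max else min(n_components, rank_max)
  sv <- svd(xc, nu = nc, nv = nc)
  d <- sv$d[seq_len(nc)]
  # eigenvalues of the covariance about mu (divisor n - 1, as in prcomp)
  eig <- d^2 / (n - 1L)
  total_var <- sum(sv$d^2) / (n - 1L)
  loadings <- sv$v
  scores <- sv$u %*% diag(d, nc)
  # deterministic sign: largest |loading| entry positive per component
  for (j in seq_len(nc)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- if (total_var > 0) eig / total_var else rep(0, nc)
  structure(list(mean_vector = mu, eigenvalues = eig, loadings = loadings,
                 scores = scores, variance_fraction = vf,
                 cumulative_fraction = cumsum(vf), total_variance = total_var,
                 k = k, m = m, n_obs = n),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  nshow <- min(5L, length(x$variance_fraction))
  cat(sprintf("Shape PCA: %d observations, %d components\n", x$n_obs,
              length(x$eigenvalues)))
  cat("  variance fraction:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(nshow)]),
            collapse = " "), "...\n")
  invisible(x)
}

#' Reconstruct configurations from PCA scores
#'
#' Inverse of [shape_pca()]: `mean_vector + scores %*% t(loadings)`,
#' reshaped to k x m landmark matrices.
#'
#' @param pca a `shape_pca`.
#' @param scores numeric vector (one observation) or matrix (rows =
#'   observations); columns beyond those supplied are taken as 0.
#' @return a k x m matrix, or a list of them when `scores` has several rows.
#' @export
pca_reconstruct <- function(pca, scores) {
  s <- if (is.null(dim(scores))) matrix(scores, nrow = 1L) else as.matrix(scores)
  nc <- ncol(s)
  if (nc > ncol(pca$loadings)) stop("more scores than components")
  v <- sweep(s %*% t(pca$loadings[, seq_len(nc), drop = FALSE]), 2L,
             pca$mean_vector, `+`)
  out <- lapply(seq_len(nrow(v)), function(i)
    devectorize_config(v[i, ], pca$k, pca$m))
  if (length(out) == 1L) out[[1L]] else out
}
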