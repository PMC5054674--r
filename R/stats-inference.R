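# Shared two-group permutation engine. Y is n x p; returns the observed
# trace R-squared (between-group SS over total SS, Goodall-type on the
# Euclidean embedding) and permuted values, all from one indicator-matrix
# multiplication so large n_perm stays cheap.
perm_rsq_engine <- function(Y, groups, n_perm, seed) {
  Y <- as.matrix(Y)
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  n <- nrow(Y)
  if (length(g) != n) stop("groups length must match observations")
  n1 <- sum(g == levels(g)[1L]); n2 <- n - n1
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group")
  m <- colMeans(Y)
  tot <- sum(sweep(Y, 2L, m)^2)
  if (tot == 0) stop("undefined R-squared: constant response")

  between <- function(sel1) {
    m1 <- colMeans(Y[sel1, , drop = FALSE])
    m2 <- colMeans(Y[!sel1, , drop = FALSE])
    n1 * sum((m1 - m)^2) + n2 * sum((m2 - m)^2)
  }
  obs <- between(g == levels(g)[1L]) / tot

  perm <- with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                  integer(n1))                       # n1 x n_perm
    P <- matrix(0, n_perm, n)
    P[cbind(rep(seq_len(n_perm), each = n1), as.vector(idx))] <- 1
    S1 <- P %*% Y                                    # n_perm x p group-1 sums
    m1 <- S1 / n1
    m2 <- sweep(-S1, 2L, colSums(Y), `+`) / n2
    (n1 * rowSums(sweep(m1, 2L, m, `-`)^2) +
     n2 * rowSums(sweep(m2, 2L, m, `-`)^2)) / tot
  })
  list(r_squared = obs, perm = perm,
       p_value = (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm))
}

#' Permutation ANOVA for a two-group scalar response
#'
#' Effect size is \eqn{R^2} = between-group sum of squares over total sum
#' of squares; significance by random permutation of group labels, with
#' \eqn{p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\}) / (1 + n_{perm})}.
#' Fully reproducible given `seed`.
#'
#' @param y numeric response, one value per subject.
#' @param groups two-level factor (or coercible).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutation draw.
#' @return list of class `perm_test`: `r_squared`, `p_value`, `n_perm`,
#'   `kind = "univariate"`.
#' @export
perm_anova <- function(y, groups, n_perm = 999L, seed = 1L) {
  res <- perm_rsq_engine(matrix(as.numeric(y), ncol = 1L), groups,
                         n_perm, seed)
  structure(list(r_squared = res$r_squared, p_value = res$p_value,
                 n_perm = n_perm, kind = "univariate"),
            class = "perm_test")
}

#' Permutation MANOVA (trace statistic) for a two-group multivariate response
#'
#' Multivariate \eqn{R^2} is the trace of the between-group cross-product
#' matrix over the trace of the total cross-product — the Goodall-type
#' statistic used on Euclidean embeddings in geometric morphometrics
#' (identical to the distance-based partitioning of `vegan::adonis2` with
#' Euclidean distances). Reduces exactly to [perm_anova()] for a single
#' column.
#'
#' @param Y numeric matrix, one row per subject.
#' @inheritParams perm_anova
#' @return list of class `perm_test` with `kind = "multivariate"`.
#' @export
perm_manova <- function(Y, groups, n_perm = 999L, seed = 1L) {
  res <- perm_rsq_engine(Y, groups, n_perm, seed)
  structure(list(r_squared = res$r_squared, p_value = res$p_value,
                 n_perm = n_perm, kind = "multivariate"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation %s test: R-squared = %.4f, p = %.4g (%d permutations)\n",
              x$kind, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

#' Per-feature two-group permutation ANOVA
#'
#' Runs [perm_anova()] on every column of `X` with a shared permutation
#' draw; used by the univariate association filter and the per-time
#' per-PC significance profiles.
#'
#' @param X numeric matrix, subjects x features.
#' @inheritParams perm_anova
#' @return data frame: feature, r_squared, p_value.
#' @export
perm_anova_features <- function(X, groups, n_perm = 999L, seed = 1L) {
  X <- as.matrix(X)
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  n <- nrow(X)
  n1 <- sum(g == levels(g)[1L]); n2 <- n - n1
  m <- colMeans(X)
  tot <- colSums(sweep(X, 2L, m)^2)
  sel1 <- g == levels(g)[1L]
  bet <- function(S1) {
    m1 <- S1 / n1
    m2 <- sweep(-S1, 2L, colSums(X), `+`) / n2
    n1 * sweep(m1, 2L, m, `-`)^2 + n2 * sweep(m2, 2L, m, `-`)^2
  }
  obs <- as.vector(bet(matrix(colSums(X[sel1, , drop = FALSE]),
                              nrow = 1L))) / tot
  perm <- with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                  integer(n1))
    P <- matrix(0, n_perm, n)
    P[cbind(rep(seq_len(n_perm), each = n1), as.vector(idx))] <- 1
    bet(P %*% X) / rep(tot, each = n_perm)
  })
  dim(perm) <- c(n_perm, ncol(X))
  p <- (1 + colSums(perm >= rep(obs - 1e-12, each = n_perm))) / (1 + n_perm)
  # constant features carry no association signal
  p[tot == 0] <- 1; obs[tot == 0] <- 0
  data.frame(feature = seq_len(ncol(X)), r_squared = obs, p_value = p)
}

#' Spearman rank correlation with a permutation p-value
#'
#' Rank correlation with midranks for ties; the p-value is obtained by
#' permuting one variable (seeded), which stays valid at the small n of
#' clinical cohorts.
#'
#' @param x,y numeric vectors, length >= 4.
#' @param n_perm permutations for the two-sided p-value.
#' @param seed RNG seed.
#' @return list: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y, n_perm = 999L, seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 paired observations")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(rxc * ryc[sample.int(length(ryc))]) / denom, 0))
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (1 + n_perm)
  list(rho = rho, p_value = p, n = length(x))
}

#' Correlation of within-subject (mean-centered) series
#'
#' Centers each subject's series on its own mean before pooling, so the
#' correlation reflects within-cycle covariation only — between-subject
#' level differences are removed entirely.
#'
#' @param x,y numeric vectors of matched (subject, time) observations.
#' @param subject subject identifier per observation.
#' @param method correlation type after centering.
#' @return list: `rho`, `p_value`, `n_obs`, `n_subjects`.
#' @export
mean_centered_correlation <- function(x, y, subject,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) != length(subject))
    stop("x, y and subject must have equal length")
  singles <- names(which(table(subject) < 2L))
  if (length(singles))
    warning("subjects with a single observation contribute zeros: ",
            paste(singles, collapse = ", "))
  xc <- x - ave(x, subject)
  yc <- y - ave(y, subject)
  ct <- cor.test(xc, yc, method = method, exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_obs = length(x), n_subjects = length(unique(subject)))
}

#' Per-time group tests on deformation PC scores
#'
#' The per-homologous-time group inference: at each of the 12 times, a
#' permutation MANOVA on the first `n_pcs` deformation PC scores and
#' per-PC univariate ANOVAs.
#'
#' @param dpca a `deformation_pca`.
#' @param n_pcs leading PCs entering the MANOVA (default 10).
#' @param n_perm,seed permutation controls.
#' @param adjust optional p-value adjustment (`"none"` or `"BH"`) applied
#'   to the per-PC univariate p-values within each time.
#' @return list: `manova` (data frame time_index, r_squared, p_value),
#'   `univariate` (data frame time_index, pc, r_squared, p_value).
#' @export
per_time_tests <- function(dpca, n_pcs = 10L, n_perm = 999L, seed = 1L,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  arr <- deformation_score_array(dpca, n_components = n_pcs)
  groups <- attr(arr, "groups")
  nt <- dim(arr)[2L]
  man <- vector("list", nt); uni <- vector("list", nt)
  for (t in seq_len(nt)) {
    X <- arr[, t, , drop = TRUE]
    res <- perm_manova(X, groups, n_perm = n_perm, seed = seed + t)
    man[[t]] <- data.frame(time_index = t, r_squared = res$r_squared,
                           p_value = res$p_value)
    u <- perm_anova_features(X, groups, n_perm = n_perm, seed = seed + t)
    if (adjust == "BH") u$p_value <- p.adjust(u$p_value, "BH")
    uni[[t]] <- data.frame(time_index = t, pc = u$feature,
                           r_squared = u$r_squared, p_value = u$p_value)
  }
  list(manova = do.call(rbind, man), univariate = do.call(rbind, uni))
}
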