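# RBF bandwidth: 1 / (n_features * mean feature variance) — the "scale"
# heuristic. Falls back to 1/n_features for constant data.
rbf_gamma <- function(X) {
  v <- mean(apply(X, 2L, var))
  if (!is.finite(v) || v <= 0) return(1 / ncol(X))
  1 / (ncol(X) * v)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(X, fit) {
  sweep(sweep(X, 2L, fit$mu), 2L, fit$sd, `/`)
}

#' Univariate association filtering
#'
#' Feature selection by per-feature two-group permutation ANOVA: features
#' whose p-value does not exceed `alpha` are retained, in their original
#' order. An empty selection is returned with a warning (callers fall back
#' to all features).
#'
#' @param X subjects x features matrix.
#' @param labels two-level group factor.
#' @param alpha p-value cut-off (default 0.05).
#' @param n_perm,seed permutation controls.
#' @return integer vector of selected feature indices.
#' @export
uaf_select <- function(X, labels, alpha = 0.05, n_perm = 999L, seed = 1L) {
  res <- perm_anova_features(X, labels, n_perm = n_perm, seed = seed)
  sel <- which(res$p_value <= alpha)
  if (length(sel) == 0L)
    warning("UAF selected no features at alpha = ", alpha)
  sel
}

#' Fit and evaluate an RBF-kernel SVM with the full metric suite
#'
#' Radial-basis Gaussian kernel with cost `C` (default 1) and the scale
#' bandwidth heuristic. Reports in-sample accuracy, sensitivity and
#' specificity (positive class = the disease group), AUC from the decision
#' values, and the leave-one-subject-out cross-validation error from
#' per-fold refits; features are standardized inside each fold. In-sample
#' and cross-validated figures are both reported, clearly distinguished —
#' in-sample metrics are optimistic by construction.
#'
#' @param X subjects x features matrix.
#' @param labels two-level factor; `positive` names the disease class.
#' @param C SVM cost parameter.
#' @param gamma RBF bandwidth; default is the scale heuristic.
#' @param positive positive-class label (default `"HCM"` when present,
#'   otherwise the second factor level).
#' @param loocv compute the leave-one-out error (default TRUE).
#' @param select_in_fold optional function(X_train, labels_train) returning
#'   feature indices, re-run inside every LOOCV fold so held-out subjects
#'   never influence selection.
#' @param seed RNG seed (the fit itself is deterministic; the seed guards
#'   any downstream consumers).
#' @return list of class `classification_report`: `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `loocv_error`, `n_features`,
#'   `positive`.
#' @export
svm_evaluate <- function(X, labels, C = 1, gamma = NULL, positive = NULL,
                         loocv = TRUE, select_in_fold = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("invalid design: need exactly two classes")
  if (is.null(positive))
    positive <- if ("HCM" %in% levels(y)) "HCM" else levels(y)[2L]
  if (!positive %in% levels(y)) stop("positive class not present")

  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  g <- gamma %||% rbf_gamma(Xs)
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = C, gamma = g,
                    scale = FALSE)
  pred <- predict(fit, Xs, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  # orient decision values so larger means more positive-class
  if (colnames(attr(pred, "decision.values"))[1L] !=
      paste(positive, setdiff(levels(y), positive), sep = "/"))
    dv <- -dv
  tp <- sum(pred == positive & y == positive)
  tn <- sum(pred != positive & y != positive)
  acc <- mean(pred == y)
  sens <- tp / sum(y == positive)
  spec <- tn / sum(y != positive)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = y == positive, predictor = dv,
    quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))))

  loocv_error <- NA_real_
  if (loocv) {
    n <- nrow(X)
    wrong <- logical(n)
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
      cols <- seq_len(ncol(X))
      if (!is.null(select_in_fold)) {
        cols <- select_in_fold(Xtr, ytr)
        if (length(cols) == 0L) cols <- seq_len(ncol(X))
      }
      sti <- standardize_fit(Xtr[, cols, drop = FALSE])
      Xtri <- standardize_apply(Xtr[, cols, drop = FALSE], sti)
      fiti <- e1071::svm(Xtri, ytr, kernel = "radial", cost = C,
                         gamma = rbf_gamma(Xtri), scale = FALSE)
      xte <- standardize_apply(X[i, cols, drop = FALSE], sti)
      wrong[i] <- predict(fiti, xte) != y[i]
    }
    loocv_error <- mean(wrong)
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 auc = auc, loocv_error = loocv_error,
                 n_features = ncol(X), positive = positive),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "SVM report: accuracy %.3f, sens %.3f, spec %.3f, AUC %.3f, LOOCV error %.3f (%d features, positive = %s)\n",
    x$accuracy, x$sensitivity, x$specificity, x$auc, x$loocv_error,
    x$n_features, x$positive))
  invisible(x)
}

#' Per-homologous-time classification of deformation PC scores
#'
#' At each of the 12 homologous times: take the first `n_pcs` deformation
#' PC scores, filter them by univariate association ([uaf_select()]), and
#' evaluate an RBF SVM. Headline metrics use the filter fitted on the full
#' data; the LOOCV error re-runs the filter inside each fold so feature
#' selection cannot leak the held-out subject.
#'
#' @param dpca a `deformation_pca` (or a subjects x 12 x components score
#'   array from [deformation_score_array()] with a `groups` attribute).
#' @param labels group labels per subject; defaults to the array's groups.
#' @param n_pcs leading PCs offered to the filter (default 50, truncated
#'   with a warning when fewer are available).
#' @param alpha UAF cut-off.
#' @param C,gamma SVM parameters.
#' @param n_perm,seed permutation/reproducibility controls.
#' @param uaf_in_fold refit the filter inside each LOOCV fold (default
#'   TRUE); FALSE mimics a single global filter.
#' @return data frame with one row per time: time_index, accuracy,
#'   sensitivity, specificity, auc, loocv_error, n_selected; attribute
#'   `selected` lists the surviving PC indices per time.
#' @export
per_time_classification <- function(dpca, labels = NULL, n_pcs = 50L,
                                    alpha = 0.05, C = 1, gamma = NULL,
                                    n_perm = 999L, seed = 1L,
                                    uaf_in_fold = TRUE) {
  arr <- if (inherits(dpca, "deformation_pca")) {
    avail <- ncol(dpca$pca$scores)
    if (avail < n_pcs) {
      warning("only ", avail, " components available; truncating n_pcs")
      n_pcs <- avail
    }
    deformation_score_array(dpca, n_components = n_pcs)
  } else dpca
  labels <- labels %||% attr(arr, "groups")
  nt <- dim(arr)[2L]
  rows <- vector("list", nt)
  selected <- vector("list", nt)
  for (t in seq_len(nt)) {
    X <- arr[, t, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
    sel <- uaf_select(X, labels, alpha = alpha, n_perm = n_perm,
                      seed = seed + t)
    if (length(sel) == 0L) sel <- seq_len(ncol(X))
    selector <- if (uaf_in_fold)
      function(Xtr, ytr) uaf_select(Xtr, ytr, alpha = alpha,
                                    n_perm = n_perm, seed = seed + t)
    else NULL
    rep_t <- suppressWarnings(
      svm_evaluate(X[, sel, drop = FALSE], labels, C = C, gamma = gamma,
                   select_in_fold = NULL, seed = seed + t, loocv = FALSE))
    loocv_rep <- suppressWarnings(
      svm_evaluate(X, labels, C = C, gamma = gamma,
                   select_in_fold = selector, seed = seed + t))
    rows[[t]] <- data.frame(time_index = t, accuracy = rep_t$accuracy,
                            sensitivity = rep_t$sensitivity,
                            specificity = rep_t$specificity,
                            auc = rep_t$auc,
                            loocv_error = loocv_rep$loocv_error,
                            n_selected = length(sel))
    selected[[t]] <- sel
  }
  out <- do.call(rbind, rows)
  attr(out, "selected") <- selected
  out
}

#' SVM classification of trajectory attributes
#'
#' One classification report per whole-cycle trajectory attribute
#' (trajectory-shape PC1 and trajectory centroid size by default) — no
#' homologous times are involved, the attributes summarise the entire LA
#' revolution.
#'
#' @param attributes a `trajectory_attributes` (or its `table`).
#' @param features attribute columns to classify on.
#' @param labels group labels; default the table's `group`.
#' @param C,gamma,seed SVM controls.
#' @return data frame: one row per attribute with the metric suite.
#' @export
trajectory_attribute_classification <- function(attributes,
                                                features = c("shape_pc1", "size"),
                                                labels = NULL, C = 1,
                                                gamma = NULL, seed = 1L) {
  tab <- if (inherits(attributes, "trajectory_attributes")) attributes$table
         else attributes
  labels <- labels %||% tab$group
  rows <- lapply(features, function(f) {
    rep_f <- svm_evaluate(matrix(tab[[f]], ncol = 1L), labels, C = C,
                          gamma = gamma, seed = seed)
    data.frame(attribute = f, accuracy = rep_f$accuracy,
               sensitivity = rep_f$sensitivity,
               specificity = rep_f$specificity, auc = rep_f$auc,
               loocv_error = rep_f$loocv_error)
  })
  do.call(rbind, rows)
}
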