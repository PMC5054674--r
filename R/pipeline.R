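#' Configuration of an end-to-end analysis run
#'
#' Collects every tunable of the pipeline with its default, so a run is
#' fully reproducible from its config (all randomness is derived from
#' `seed`).
#'
#' @param spec a [cohort_spec()] for the synthetic cohort, or `NULL` when
#'   `cohort` is supplied directly to [run_pipeline()].
#' @param interp_method score interpolation, `"spline"` or `"linear"`.
#' @param q trajectory dimension (leading deformation PCs used as
#'   trajectory landmarks).
#' @param anchors trajectory GPA anchor landmarks.
#' @param n_pcs_tests deformation PCs entering the per-time MANOVA.
#' @param n_pcs_classify deformation PCs offered to the per-time
#'   classifier.
#' @param n_pcs_trajectory trajectory-shape PCs entering the trajectory
#'   MANOVA.
#' @param alpha UAF p-value cut-off.
#' @param C SVM cost.
#' @param n_perm permutations for all tests.
#' @param seed master analysis seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), interp_method = "spline",
                       q = 3L, anchors = c(1L, 5L, 9L), n_pcs_tests = 10L,
                       n_pcs_classify = 50L, n_pcs_trajectory = 10L,
                       alpha = 0.05, C = 1, n_perm = 999L, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full LA trajectory analysis pipeline
#'
#' Orchestrates simulate (optional) -> homologize -> linear shift +
#' deformation PCA -> trajectories -> volumetrics -> per-time inference ->
#' classification, returning every stage artifact plus a machine-readable
#' summary. Deterministic given the config.
#'
#' @param config a [run_config()].
#' @param cohort optional list of [cine_sequence()]; when `NULL` a
#'   synthetic cohort is generated from `config$spec`.
#' @param out_dir optional directory; when given, the summary is written
#'   there as `summary.json` and per-stage tables as CSV.
#' @return list of class `pipeline_run` with elements `cohort`,
#'   `homologized`, `deformation`, `trajectories`, `attributes`,
#'   `volumetrics`, `tests`, `classification`, `correlations`, `summary`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         out_dir = NULL) {
  if (is.null(cohort)) {
    if (is.null(config$spec)) stop("config error: no cohort and no spec")
    cohort <- generate_cohort(config$spec)
  }

  hom <- homologize_cohort(cohort, method = config$interp_method)
  dpca <- deformation_analysis(hom$series)

  trajectories <- cohort_trajectories(dpca, q = config$q)
  attrs <- trajectory_attributes(trajectories, anchors = config$anchors,
                                 n_components = config$n_pcs_trajectory)

  vol <- lapply(hom$series, function(s) {
    ind <- la_function_indicators(volume_curve(s))
    data.frame(subject_id = s$subject_id, group = s$group,
               v_max = ind$v_max, v_min = ind$v_min, v_preA = ind$v_preA,
               ef_global = ind$ef_global, ef_reservoir = ind$ef_reservoir,
               ef_conduit = ind$ef_conduit, ef_booster = ind$ef_booster,
               booster_abs = ind$booster_abs)
  })
  vol <- do.call(rbind, vol)

  tests <- per_time_tests(dpca, n_pcs = config$n_pcs_tests,
                          n_perm = config$n_perm, seed = config$seed)
  groups <- attrs$table$group
  traj_tests <- list(
    shape_pc1 = perm_anova(attrs$table$shape_pc1, groups,
                           n_perm = config$n_perm, seed = config$seed + 101L),
    shape_manova = perm_manova(
      as.matrix(attrs$table[, grep("^shape_pc", names(attrs$table))]),
      groups, n_perm = config$n_perm, seed = config$seed + 102L),
    size = perm_anova(attrs$table$size, groups, n_perm = config$n_perm,
                      seed = config$seed + 103L),
    angle_12 = perm_anova(attrs$table$angle_12, groups,
                          n_perm = config$n_perm, seed = config$seed + 104L),
    angle_13 = perm_anova(attrs$table$angle_13, groups,
                          n_perm = config$n_perm, seed = config$seed + 105L))

  per_time <- per_time_classification(dpca, n_pcs = config$n_pcs_classify,
                                      alpha = config$alpha, C = config$C,
                                      n_perm = config$n_perm,
                                      seed = config$seed + 200L)
  traj_class <- trajectory_attribute_classification(attrs, C = config$C,
                                                    seed = config$seed + 300L)

  # Spearman correlations of trajectory attributes with the volumetric
  # indicators, across subjects
  indicators <- c("ef_global", "ef_reservoir", "ef_conduit", "ef_booster",
                  "booster_abs")
  correlations <- do.call(rbind, lapply(indicators, function(ind) {
    s1 <- spearman_cor(attrs$table$size, vol[[ind]],
                       seed = config$seed + 400L)
    s2 <- spearman_cor(attrs$table$shape_pc1, vol[[ind]],
                       seed = config$seed + 401L)
    data.frame(indicator = ind, rho_size = s1$rho, p_size = s1$p_value,
               rho_shape_pc1 = s2$rho, p_shape_pc1 = s2$p_value)
  }))

  summary <- list(
    n_subjects = length(cohort),
    n_landmarks = nrow(cohort[[1L]]$frames[[1L]]),
    deformation_variance_pct = round(100 * dpca$pca$variance_fraction[1:10], 3),
    per_time_manova = tests$manova,
    trajectory_shape_pc1 = traj_tests$shape_pc1[c("r_squared", "p_value")],
    trajectory_size = traj_tests$size[c("r_squared", "p_value")],
    per_time_classification = per_time,
    trajectory_classification = traj_class,
    volumetrics_by_group = aggregate(
      vol[, c("v_max", "ef_global", "ef_reservoir", "ef_conduit",
              "ef_booster", "booster_abs")],
      by = list(group = vol$group), FUN = mean),
    correlations = correlations)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write.csv(vol, file.path(out_dir, "volumetrics.csv"), row.names = FALSE)
    write.csv(per_time, file.path(out_dir, "per_time_classification.csv"),
              row.names = FALSE)
    write.csv(tests$manova, file.path(out_dir, "per_time_manova.csv"),
              row.names = FALSE)
    write.csv(attrs$table, file.path(out_dir, "trajectory_attributes.csv"),
              row.names = FALSE)
  }

  structure(list(cohort = cohort, homologized = hom, deformation = dpca,
                 trajectories = trajectories, attributes = attrs,
                 volumetrics = vol,
                 tests = c(tests, list(trajectory = traj_tests)),
                 classification = list(per_time = per_time,
                                       trajectory = traj_class),
                 correlations = correlations, summary = summary,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("LA trajectory pipeline run: %d subjects, %d landmarks\n",
              x$summary$n_subjects, x$summary$n_landmarks))
  cat(sprintf("  deformation PC1 variance: %.1f%%\n",
              x$summary$deformation_variance_pct[1L]))
  cat(sprintf("  trajectory shape PC1: R2 = %.3f, p = %.3g\n",
              x$summary$trajectory_shape_pc1$r_squared,
              x$summary$trajectory_shape_pc1$p_value))
  best <- which.max(x$classification$per_time$accuracy)
  cat(sprintf("  best per-time accuracy: %.2f (time %d), AUC %.2f\n",
              x$classification$per_time$accuracy[best], best,
              x$classification$per_time$auc[best]))
  invisible(x)
}
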