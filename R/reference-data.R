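#' Reference deformation-PCA variance table
#'
#' Per-component variance percentages of the deformation PCA (GPA in SSS +
#' linear shift + PCA) reported for the original clinical cohort of 46
#' controls and 22 HCM patients: eigenvalue, percent variance and
#' cumulative percent for the first 10 PCs. Shipped as a plain-text table
#' for internal-consistency checks (the cumulative column must equal the
#' running sum of the per-PC column) and for comparing synthetic-cohort
#' variance profiles against a clinical anchor.
#'
#' @return data frame: `pc`, `eigenvalue`, `variance_pct`,
#'   `cumulative_pct`.
#' @export
reference_deformation_variance <- function() {
  path <- system.file("extdata", "reference_deformation_variance.tsv",
                      package = "lamorph", mustWork = TRUE)
  read.delim(path)
}
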