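# lamorph

Geometric morphometrics of left-atrial (LA) deformation trajectories from
3D speckle-tracking echocardiography (3DSTE) landmark clouds.

## The problem

3DSTE delivers, for each subject and cardiac cycle, a cine of endocardial
landmark clouds (by convention 36 rings × 36 points + apex = 1297
landmarks). Conventional global strain parameters reduce this to per-frame
averages referenced to the end-systolic frame, discarding the actual LA
geometry and the geometry of its motion. `lamorph` implements a full
shape-analytic alternative aimed at studies of LA dysfunction (e.g. in
hypertrophic cardiomyopathy, HCM):

1. **Temporal homology.** Three electromechanical events per cycle — R
   peak, LA end-diastolic (maximum) volume, P peak — are strictly
   homologous across subjects. With 3 equally spaced times inserted into
   each of the three phases (reservoir, conduit, booster pump), every
   subject is resampled at 12 homologous times by interpolating its
   per-frame shape PC scores.
2. **GPA in size-and-shape space (SSS).** Configurations are superimposed
   by translation and proper rotation only — size is retained as a
   biological attribute. Aligned SSS configurations lie in the Euclidean
   tangent space at the grand mean (GM), so PCA applies directly.
3. **Linear-shift parallel transport.** Each subject's within-cycle
   deformations are detached from its own mean shape and re-attached to
   the GM: `GM + (x_t − x̄_subject)`. This removes inter-individual shape
   differences; PCA of the transported shapes (deformation PCA) shows pure
   deformation, with end-systole and end-diastole both recognized as
   deformed states.
4. **Trajectory analysis.** The first q (default 3) deformation PC scores
   at the 12 times form a 12-landmark configuration per subject — the
   shape of the motion. A second-order GPA in shape space, aligning on the
   strictly homologous landmarks 1, 5, 9 only (the others ride along
   passively), yields trajectory-shape PCs, centroid size, and orientation
   angles of the R→ED vector on the PC1/PC2 and PC1/PC3 planes.
5. **Inference and classification.** Permutation ANOVA/MANOVA (trace
   statistic, R² effect sizes) at each homologous time and on trajectory
   attributes; Hoit-style phasic volumetric indicators; univariate
   association filtering + RBF-kernel SVM (C = 1) with accuracy,
   sensitivity, specificity, AUC and leave-one-subject-out error.

Because clinical 3DSTE datasets are rarely shareable, the package includes
a synthetic cohort generator (`cohort_spec()`, `generate_cohort()`) that
emulates the two-group structure — case dilation, reduced phasic ejection
fractions, presence/absence of the pre-P-peak conduit flattening — so the
entire pipeline is testable end to end.

## Worked example

```r
library(lamorph)

spec <- cohort_spec(n_control = 10, n_case = 10,
                    rings = 12, points_per_ring = 12, seed = 20161007)
run <- run_pipeline(run_config(spec = spec, n_pcs_classify = 20, seed = 1))
print(run)
#> LA trajectory pipeline run: 20 subjects, 145 landmarks
#>   deformation PC1 variance: 95.8%
#>   trajectory shape PC1: R2 = 0.952, p = 0.001
#>   best per-time accuracy: 1.00 (time 1), AUC 1.00

run$summary$volumetrics_by_group
#>     group  v_max ef_global ef_reservoir ef_conduit ef_booster booster_abs
#> 1 Control  59.72     49.52        98.16      32.38      25.33       10.24
#> 2     HCM 134.74     29.85        42.56      13.50      18.90       22.00
```

The volumetric table reads as physiology: case LA volumes are more than
twofold dilated, their global/reservoir/conduit ejection fractions are
reduced, and the absolute booster volume (ml) is increased although the
booster ejection fraction is only mildly affected. The trajectory-shape
PC1 separates groups (permutation ANOVA R² = 0.95, p = 0.001 on this
synthetic cohort) because the conduit-phase flattening bends the control
trajectories at the homologous landmarks between end-diastole and the P
peak, and the generator gives that bend to controls only. On synthetic
cohorts this scale of separation is by construction much stronger than in
clinical data.

Individual stages are exported (`homologize_cohort()`,
`deformation_analysis()`, `cohort_trajectories()`,
`trajectory_attributes()`, `volume_curve()`, `la_function_indicators()`,
`per_time_tests()`, `per_time_classification()`, ...), and cines can be
exchanged via a plain CSV + JSON format (`write_cine()` / `read_cine()`).

## Vignette

`vignettes/la-trajectory-analysis.Rmd` documents the model, its
assumptions, the numerical choices (GPA tolerances, interpolation scheme,
anchor-only alignment, volume integration), what the synthetic generator
does and does not emulate, and known limitations.
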