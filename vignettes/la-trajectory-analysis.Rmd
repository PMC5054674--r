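---
title: "Shaping left-atrial motion: deformation trajectories in size-and-shape space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shaping left-atrial motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamorph)
```

## The model

`lamorph` analyses cyclic clouds of homologous endocardial landmarks
(k × 3 configuration matrices, mm) sampled by 3D speckle-tracking
echocardiography on a ring/apex grid. The analysis chain is:

**GPA in the size-and-shape space (SSS).** Generalized Procrustes Analysis
superimposes configurations by translation and proper rotation; the
classic shape space (SS) additionally scales each configuration to unit
centroid size, projecting onto a hypersphere. The SSS omits that third
projection: geodesics between aligned configurations are straight lines,
so aligned SSS configurations already sit in the Euclidean tangent space
at the grand mean (GM) and PCA applies without any further projection.
Size is deliberately retained — cavity size is itself a functional
attribute of the LA.

**Temporal homology.** Anatomical homology of landmarks is extended in
time: the R peak, the LA end-diastolic (maximum) volume and the P peak are
electromechanical events identifiable in every subject, and they delimit
the three phasic LA functions (reservoir, conduit, booster pump). Three
equally spaced times inside each phase give a 12-point grid per cycle
(`homologous_time_grid()`); the next R peak opens the next cycle and is
excluded. Each subject's per-frame PC scores from a pooled SSS GPA + PCA
over all observed frames are interpolated at its own grid and the 12
shapes rebuilt from the loadings (`reconstruct_homologous_series()`).

**Linear-shift parallel transport.** Comparing deformations requires
removing inter-individual shape differences. Exact parallel transport on
Kendall shape space is replaced by its tangent-plane linearization, the
linear shift (LS): each subject's within-cycle deviations from its own
mean shape are re-attached to the GM,
\( \tilde{x}_t = \mathrm{GM} + (x_t - \bar{x}_{\text{subject}}) \).
The approximation is appropriate for echocardiographic data, where
within-cycle deformations are small relative to the curvature scale of the
shape manifold. After the shift, every subject's transported trajectory
has mean exactly GM, and PCA of the transported shapes about the GM
(`deformation_analysis()`) exposes pure deformation modes: both
end-systole and end-diastole appear as deformed states of the common
mannequin, unlike conventional strain outputs which fix end-systole as an
undeformed zero.

**Trajectory shape, size, orientation.** The first q deformation PC scores
at the 12 times are treated as a 12-landmark configuration in
q dimensions. A second-order GPA — this time in SS, because here pure
trajectory *shape* is the object — estimates translation, scale and
rotation from the three strictly homologous landmarks (1, 5, 9) only;
the interpolated landmarks are passively transformed. This prevents
imprecision in the interpolated times from distorting the alignment.
Trajectory size is the centroid size of the raw 12 × q configuration;
orientation is the direction of the vector from landmark 1 (R peak) to
landmark 5 (end-diastole) on the PC1/PC2 and PC1/PC3 planes.

**Inference and classification.** Group tests are permutational
throughout: R² = between-group SS / total SS, and for multivariate
responses the trace (Goodall-type) statistic on the Euclidean embedding —
the morphometric convention, robust when variables outnumber subjects, and
identical to distance-based partitioning with Euclidean distances (the
test suite cross-checks against `vegan::adonis2`). Classification uses an
RBF-kernel SVM at C = 1 after univariate association filtering (UAF,
p ≤ 0.05 per feature), per homologous time on the leading deformation PCs
and once on the whole-cycle trajectory attributes.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `tol`, `max_iter` (GPA) | 1e-10, 200 | Frobenius change of the mean; the alternating scheme converges in a handful of iterations on real-scale data |
| interpolation | natural cubic spline | reproduces observed values exactly and is smooth across the cycle; `"linear"` available |
| `q` | 3 | trajectory dimension; any larger q gives hyper-shapes, at the cost of interpretability |
| `anchors` | 1, 5, 9 | the strictly homologous events; scale is taken from the anchor sub-configuration's centroid size, since the anchors define all three transform components |
| `n_pcs_tests` | 10 | deformation PCs entering the per-time MANOVA |
| `n_pcs_classify` | 50 | deformation PCs offered to UAF + SVM per time |
| `n_pcs_trajectory` | 10 | trajectory-shape PCs in the trajectory MANOVA; 5 is a documented alternative and both are exposed, as the choice is genuinely open |
| `alpha` | 0.05 | UAF cut-off (p ≤ alpha) |
| `C`, gamma | 1, scale heuristic | RBF SVM cost; gamma = 1/(p · mean feature variance), configurable |
| `n_perm` | 999 | permutations; p-values floor at 1/(n_perm+1) |

## Design choices where the construction was open

- **Pooled vs per-subject GPA.** The per-frame decomposition uses a single
  pooled SSS GPA over all frames of all subjects: inter-subject
  comparability requires one common coordinate frame, and the subsequent
  linear shift removes the inter-individual offsets the pooling leaves in.
- **Shift reference.** The subject reference subtracted by the LS is the
  mean of its 12 homologous shapes, which makes "trajectories centered on
  the GM" literal (the per-subject mean of transported shapes equals the
  GM exactly, a property the tests assert at 1e-12). `reference =
  "first_frame"` is available for deformation-relative-to-R-peak analyses.
- **GM definition.** The mannequin is the mean of the homologous-time
  reconstructions (12 × n subjects shapes), not of the raw frames, so
  subjects with higher frame rates do not weigh more.
- **Reflections** are excluded everywhere (rotations constrained to
  det = +1): anatomical landmark clouds must not mirror.
- **Sign convention.** Each PC's largest-magnitude loading entry is made
  positive, so decompositions are deterministic across runs and platforms.
- **Volume integration.** Cavity volume closes the ring/apex surface with
  a centroid fan over the open base ring (mitral plane) and sums signed
  tetrahedra (divergence theorem), orientation-corrected to be positive.
  On a 36 × 36 sampling of an analytic sphere this is accurate to under
  1% and converges with grid refinement (asserted in the tests).
- **Phasic indicator formulas.** With v_max read at the end-diastolic
  event (grid position 5; the curve maximum overrides it, with a warning,
  only when it exceeds it by ≥ 5%), v_preA at the P peak (position 9) and
  v_min the curve minimum: global EF = 100(v_max−v_min)/v_max, reservoir
  (expansion index) = 100(v_max−v_min)/v_min, conduit EF =
  100(v_max−v_preA)/v_max, booster EF = 100(v_preA−v_min)/v_preA, absolute
  booster = v_preA−v_min. Stated explicitly here because several
  denominator conventions circulate; these are audit-ready in the code.
- **Classification honesty.** In-sample accuracy/AUC and LOOCV error are
  both reported and labelled: in-sample figures are optimistic. Inside
  every LOOCV fold the UAF is re-fitted by default, so the held-out
  subject never influences feature selection; a single global filter can
  be requested (`uaf_in_fold = FALSE`). The disease group is the positive
  class for sensitivity.
- **Degenerate inputs.** All-coincident landmark clouds, constant
  responses, single-class designs, extrapolating queries and mismatched
  landmark counts raise typed errors rather than propagating NaNs;
  GPA non-convergence warns and flags the result.

## The synthetic cohort generator

`generate_cohort()` exists so every stage is testable without clinical
data. Per subject it samples a cycle length (650–950 ms), a frame rate
(20–35 Hz, two full cycles), jittered event fractions, and a smooth
volume program: cosine reservoir rise to v_max at end-diastole, conduit
descent blending a linear fall with a smoothstep plateau (the pre-P-peak
flattening, strength `bend_amplitude` — present in controls, absent in
cases), booster drop to v_min and a small refill to the R-peak volume.
The half-ellipsoid template (36 rings × 36 points + apex) is deformed by
an anisotropic similarity field (long-axis exponent 0.4, circumferential
0.3 of the volume ratio) calibrated against the mesh volume of the
subject's perturbed template, a twist about the long axis growing with
contraction, a smooth low-order static shape perturbation (2 mm RMS), and
i.i.d. landmark noise (0.2 mm). Group defaults: 46/22 subjects, case
volumes 2.2× dilated, global EF 50% vs 30%, pre-A volume fraction
0.35 vs 0.55 (which yields reduced conduit EF and an increased absolute
booster volume in cases), twist 8° vs 3°.

What it does **not** emulate: real wall mechanics (the deformation field
is low-order and non-physiological), speckle/tracking artifacts and
dropout, fiber-driven regional heterogeneity, valve-plane through-motion,
arrhythmic beat-to-beat variability, or realistic magnitudes of
inter-subject anatomical variation. Consequently, group separations on
synthetic cohorts are far cleaner than clinical ones: passing tests show
the machinery recovers planted structure and stays calibrated under the
null, not that clinical effect sizes would be reproduced.

## Problem sizes used in the shipped checks

The test suite exercises reduced geometries (12 × 12 + apex = 145
landmarks; cohorts of 12–40 subjects) for all property checks, and the
full default cohort (68 subjects, 1297 landmarks) for the end-to-end
classification ordering; `scripts/acceptance.R` always runs the full
default cohort. Calibration checks use 200 null replicates of the
permutation tests and 40 of the UAF selection rate.

## Known limitations

- The linear shift is a first-order approximation; for organs with large
  within-cycle shape excursions relative to inter-subject spread the
  Riemannian transport would differ.
- Natural-spline interpolation assumes smooth score traces; very low
  frame rates (< ~15 Hz) under-resolve the booster phase.
- The trace MANOVA tests location differences only; dispersion
  differences between groups can masquerade as location effects in any
  permutation MANOVA of this type.
- Volumes assume the base ring is planar-ish and star-shaped about its
  centroid; strongly folded mitral annuli would need a true surface
  reconstruction.
- With 12 observations per trajectory and q = 3, trajectory-shape PCA has
  at most 33 non-trivial dimensions; retaining 10 PCs on small cohorts
  approaches saturation and the MANOVA should then be read descriptively.
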