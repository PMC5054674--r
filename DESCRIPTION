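Package: lamorph
Title: Geometric Morphometrics of Left-Atrial Deformation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of cyclic left-atrial (LA) endocardial landmark clouds
    from 3D speckle-tracking echocardiography. Builds homologous-time shape
    series from annotated electromechanical events, aligns them by
    Generalized Procrustes Analysis in the size-and-shape space, transports
    within-cycle deformations onto the grand mean by the linear-shift
    approximation of parallel transport, and summarises the resulting
    deformation trajectories by principal components, centroid size and
    orientation. Includes volumetric LA function indicators, permutation
    ANOVA/MANOVA group inference, SVM classification with univariate
    association filtering, and a synthetic cohort generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
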