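Package: midasqspr
Title: Tensor-Algebra 3D Molecular Descriptors and QSPR Modeling of
    Homogeneous Quinoline Hydrogenation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes tensor-algebra based three-dimensional molecular
    descriptors (N-tuple spatial (dis)similarity matrices with metric,
    stochastic-normalization and cutoff choices; linear, bilinear and
    quadratic local vertex invariants aggregated into global indices) and
    fits quantitative structure-property relationship (QSPR) models for
    the initial rate of homogeneous quinoline hydrogenation catalyzed by
    Ru, Rh, Os and Ir complexes. Includes genetic-algorithm descriptor
    selection with leave-one-out cross-validation fitness, a full model
    validation battery (bootstrap, Y-randomization, residual diagnostics,
    variance inflation factors, random-split robustness), applicability
    domain analysis (Williams plot, neighborhood components analysis,
    local outlier factor), the published 32-catalyst rate dataset, and
    synthetic data generators that reproduce the statistical geometry of
    the study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    car,
    jsonlite
Config/testthat/edition: 3
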