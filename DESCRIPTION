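Package: facesculpt
Title: Face-Space Sculpting by Interactive Differential Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for landmark-based face-space experiments in which a
    chooser (a human, or a simulated subject with a latent preference
    attractor) "sculpts" a preferred facial variation of a reference
    portrait through a sequence of binary choices driven by a
    differential-evolution algorithm. Provides the 11-distance face-space
    with its facial-length normalization constraint, conversions between
    inter-landmark distances and Cartesian landmark coordinates,
    moving-least-squares similarity image deformation for rendering facial
    vectors on a reference portrait, the binary-choice evolution engine,
    face-space metrics (Euclidean, Mahalanobis, angle, whitened-angle) with
    population pseudo-distances, and the statistical layer: separation
    statistics between self-consistency and inter-subject distance
    histograms, overlap probabilities, one-vector-per-subject bootstrap
    correlation matrices, principal component analysis, group comparisons
    and cross-experiment coordinate offsets. A synthetic-data module
    generates simulated cohorts with planted attractor structure and a
    programmatic portrait fixture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
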