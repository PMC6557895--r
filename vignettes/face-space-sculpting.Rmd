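---
title: "Face-space sculpting: model, engine and statistical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Face-space sculpting: model, engine and statistical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesculpt)
```

## The face space

A face is parametrized by `D = 11` inter-landmark distances
`d_0 ... d_10`, each the absolute vertical or horizontal coordinate
difference between a designated pair of the 18 facial landmarks, expressed
as a proportion of the total facial length.  The four vertical distances
`d_1 ... d_4` partition the face height (top of face to eye line, eye line
to nose end, nose end to mouth line, mouth line to chin) and obey the
normalization constraint

$$h = \sum_{i=1}^{4} d_i = 1,$$

which absorbs the overall scale of the face: the space has 10 free
dimensions.  The remaining distances are the zygomatic height offset
(`d_0`), the face, inter-eye, mouth, eye, nose and jaw widths
(`d_5 ... d_10`).  An equivalent chart uses the 10 non-redundant Cartesian
coordinates of 7 free landmarks (`cartesian_coordinates()` /
`cartesian_to_distances()` are exact inverses); the midline-landmark
abscissae and the frame-fixing coordinates (top landmark at `y = 0`, chin
at `y = 1`) are omitted.

Two conventions deserve emphasis:

* The face frame follows the **image convention**: `y` increases
  *downward*.  "Higher eyes" therefore means *smaller* `d_1`, and the
  signs of coordinate correlations must be read accordingly.
* The exact landmark pairings of the distance definitions are **data, not
  code**: `default_schema()` ships the package's reconstruction (stored as
  a `face_schema` object, serializable to YAML), and an alternative
  pairing is a configuration change.  The jaw height is the one landmark
  coordinate no distance determines; it keeps a schema default (0.85
  facial lengths).

Per-coordinate bounds default to 50%–150% of an anatomically plausible
reference vector.  `project_to_constraint()` maps arbitrary raw vectors
into the model: the constrained block is rescaled to sum to one, all
coordinates are clamped into their bounds, and rescaling of the still-free
constrained coordinates is iterated to joint feasibility.  The operation
is idempotent and exact (the constraint holds to better than `1e-9`), and
every vector the package emits passes through it.

## Image deformation

`render_face()` turns a facial vector into a portrait: target pixel
positions for the landmarks are computed from the vector (using the
reference portrait's facial length in pixels), and the reference image is
deformed so its landmarks move to those targets.  The warp is a
moving-least-squares (MLS) deformation restricted to the **similarity
class** — at every evaluation point the locally fitted transform is a
rotation plus uniform scale plus translation, with inverse-square distance
weights (exponent `alpha`, default 1, exposed in the API).  Similarity
transforms preserve local shape much better than general affine fits,
which is what keeps the deformed faces realistic.  The closed form is
implemented in `local_similarity()`; it reproduces any global similarity
of the control points to machine precision, a property the test suite
checks directly.

Evaluating the MLS map at every pixel is unnecessary: `deform_image()`
evaluates it only at the vertices of a sub-grid of at most 15 px spacing,
splits each cell into two triangles (diagonal fixed top-left to
bottom-right), and fills each destination triangle by inverse-affine
bilinear sampling of its source triangle.  Two numerical choices matter:

* **Vertex snapping.**  One lattice vertex is snapped onto each control
  point, assignments made closest-first.  The MLS map is exact at control
  points, so landmarks sit on triangulation vertices and are *pinned* to
  their targets rather than interpolated across a cell; without this,
  strongly moving landmarks could miss their targets by several pixels at
  the default grid spacing.  Fiducial round-trip tests on the synthetic
  portrait confirm sub-pixel landmark placement.
* **Backward sampling.**  Destination pixels are filled by sampling the
  source (bilinear), so the output has no holes and its intensities stay
  within the input range; the rare pixels covered by no triangle take the
  nearest covered value.  Warps that fold more than 1% of the destination
  triangles are rejected as geometrically invalid.

Images are grayscale matrices in `[0, 1]` (PNG I/O via the `png`
package); color inputs are converted with Rec. 601 luma weights.

## The sculpting engine

`run_experiment()` implements the human-in-the-loop (or simulated)
exploration.  Defaults are the reference experimental settings: population
size `N = 28`, `T = 10` generations, differential weight `mu = 0.15`,
crossover probability `rho = 1`, hence `N * T = 280` binary choices per
run.  Each generation, every member `n` proposes a DE/rand/1/bin
offspring — three distinct partners `a, b, c != n`, mutant
`f(a) + mu * (f(b) - f(c))`, binomial crossover at rate `rho` with one
coordinate always inherited from the mutant — projected back onto the
constraint surface.  Parent and offspring are presented in randomized
side order; the chooser's pick survives.  Choosers are side-blind and may
declare indifference, which conservatively retains the parent (the
tie-break also used by the deterministic simulated subject).

The simulated subject holds a latent attractor `f*` and picks the left
option with probability

$$P(\mathrm{left}) = \mathrm{logistic}\bigl(\beta \, D \,
  (d_\mathrm{right} - d_\mathrm{left})\bigr),$$

where `d` is the per-coordinate face-space distance to `f*` under the
configured metric and the factor `D = 11` makes `beta` an inverse
temperature *per coordinate* (the utility sums over coordinates).  The
scale was fixed so that `beta = 6` yields roughly 90% accuracy at typical
early-run distance gaps — a plausible psychophysical operating point —
with `beta = 0` the random null model and `beta = Inf` the deterministic
chooser.

**A property of DE/rand/1 worth knowing.**  Under random choices the
base-vector resampling of rand/1 causes genetic drift: the population
spread contracts by roughly 2% per generation even with no selection at
all, only partially offset by the `mu^2` mutation inflation.  We examined
the drift-free alternative (current/1, mutant built on the parent), but at
`T = 10` it destroys the population clusterization that the method's
convergence and subjectivity analyses rely on, so rand/1 is retained.  The
practical consequence: the null model's intra-population distance curve is
not perfectly flat but declines about 6–7 times more slowly than under a
`beta = 6` subject, so the qualitative null-versus-subject contrast is
preserved while a strict "no decreasing trend" test over many seeds does
detect the drift.

## Metrics and population statistics

`face_distance()` implements four metrics: Euclidean (per-coordinate RMS,
`||u - v|| / sqrt(D)`; the `norm = "mean"` variant divides by `D`
instead), Mahalanobis (pseudo-inverse of the coordinate covariance on its
top-`k` eigenspace, default rank 7 — the truncation found to sharpen
subject discrimination), the angle between standardized fluctuation
vectors (optionally PC-truncated), and an angle in the whitened
(Mahalanobis) frame labelled `byatt_rhodes`.  The precise historical
definition of the last metric is not restated in the sources available to
this package, so the whitened-angle fallback is clearly labelled and
swappable.  All population statistics — `intra_population_distance()`
(mean over unordered member pairs), `population_pseudo_distance()` (mean
over cross pairs; "pseudo" because a spread-out population is at nonzero
distance from itself) — are verified against brute-force double loops.

## The statistical battery

* `separation_stats()` summarizes the inter-subject (i) versus
  self-consistency (sc) distance histograms by
  `t = (mu_i - mu_sc) / sqrt(sigma_i^2 + sigma_sc^2)` (sample standard
  deviations, denominator `n - 1`) and the Gaussian overlap
  `p12 = pnorm(t)`; `empirical_p12()` estimates the same overlap
  non-parametrically (exhaustive when the pair count allows, Monte-Carlo
  otherwise, ties counting one half).
* `bootstrap_correlation()` estimates the coordinate correlation matrix
  `C_ij = <y_i y_j>` across subjects while cancelling within-attractor
  correlations: each realization keeps *one* member per subject,
  standardizes within the realization (population standard deviation, so
  the diagonal is exactly 1), and the mean, spread and sign-flip fraction
  over realizations are reported.  Two p-values accompany each element:
  the member-bootstrap `z = mean/sd` (which asks about the *realized*
  cohort and legitimately flags finite-sample correlations of order
  `1/sqrt(S)`), and `p_cohort`, which adds the across-subject variance of
  the products `y_i y_j / S` and is calibrated against a
  population-level null.  Recovery simulations show the first detects a
  planted correlation at smaller sample sizes while the second keeps the
  generative false-positive rate at its nominal level; reports should
  state which question is being asked.
* `pca_decompose()` returns eigenvalues in ascending order (the last axis
  is the most variant), rows of `E` as the principal axes with a
  deterministic sign convention (largest-magnitude entry positive), and
  `pca_project()` gives `y' = E y`.  The `h = 1` constraint appears as an
  exact null eigenvector with equal weights on `d_1 ... d_4` — a useful
  internal consistency check.
* `group_coordinate_test()` compares two groups of subjects per
  coordinate (or per PC) on subject-mean standardized vectors, Welch's t
  by default with a pooled-variance switch; standardization uses the
  pooled dataset's mean and spread.  No multiple-testing correction is
  applied by default (raw thresholds are reported), with
  Benjamini–Hochberg available via `p_adjust`.
* `cross_experiment_offset()` reports per-coordinate mean differences of
  subject means between two experiments with standard errors, the
  statistic used to identify coordinates robust to a change of reference
  portrait.

## The synthetic-data module

`sample_cohort()` + `run_synthetic_study()` stand in for human cohorts:
subjects are latent attractors drawn from a configurable multivariate
Gaussian (projected onto the constraint), optionally split into two
labelled groups with a mean offset, choosing through the logistic model
above.  Experiment tags can carry per-coordinate attractor shifts,
emulating a change of reference portrait that displaces some preferred
coordinates while leaving "robust" ones untouched.

Two cohort presets serve different purposes:

* **Emulation** (default): attractor spread 0.018 facial lengths per
  coordinate — the spread observed for sculpted coordinates in human
  cohorts — with gender-like group weights 54:39.
* **Recovery** (`attractor_dist = "uniform"`, or a bounds-scaled Gaussian
  `(hi - lo)/sqrt(12)` when a planted correlation is needed): attractors
  spanning the explorable face space, used when the question is whether
  the analysis layer detects planted structure.

The distinction is forced by an honest limitation: the `beta = 6`
simulated chooser is far noisier than real subjects.  Its algorithmic
noise floor is about 0.04 facial lengths per coordinate (self-consistency
pseudo-distance ≈ 0.065, versus ≈ 0.0067 for human subjects under the
same engine settings), so the narrow emulation cohort's 0.018 attractor
diversity is *below the simulated engine's resolution*: separation and
correlation-recovery analyses on emulation cohorts hover at chance.  Real
subjects' sub-millimeter discrimination corresponds to `beta` of order 20
or more in the package's units.  Recovery analyses therefore plant
structure on the explorable-space scale, where the pipeline detects it
decisively.  Passing recovery tests validate the statistical machinery;
they do not show that a `beta = 6` chooser resolves human-scale
subjectivity.

`make_fixture_image()` draws a deterministic cartoon portrait (smooth
elliptical head, eyes, nose, mouth over gentle sinusoidal texture) with
its features at the schema's reference landmark positions, optionally
burning in dark fiducial dots at the landmarks; it is synthetic and
replaces any real photograph in tests, examples and the command-line
`fixtures` subcommand.

## Problem sizes and reproducibility

Everything is reproducible from integer seeds (engine, cohorts, studies,
bootstrap).  The test suite exercises full-scale single runs (`N = 28`,
`T = 10`, 280 choices, ~0.05 s each) and keeps simulation studies at
modest cohort sizes (50 seeded runs for convergence and null properties;
`S = 20, m = 3` for the subjectivity ordering; `S = 60, B = 1000` for
correlation recovery; `S = 16, m = 3` for cross-experiment offsets) —
sizes chosen so each property is measured with comfortable statistical
margin while the whole suite runs in well under a minute of simulation
time.

## Known limitations

* Texture, lightness and all non-geometric degrees of freedom are fixed
  by the reference portrait; the model sculpts geometry only.
* The null model is not perfectly flat (rand/1 drift, above).
* Image I/O is 8-bit grayscale PNG.
* The engine's resolution under simulated choosers is set by `beta`; no
  empirical estimate of human choice noise is available to calibrate it,
  so `beta` should be treated as a free simulation parameter, not a fitted
  quantity.
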