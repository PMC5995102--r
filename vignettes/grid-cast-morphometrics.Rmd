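---
title: "Grid-cast morphometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-cast morphometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphowrap)
```

## The problem

Many organisms — the water flea *Daphnia* is the motivating example — offer
almost no discrete anatomical landmarks, so classical geometric
morphometrics cannot establish the point-to-point correspondence that
Procrustes-based shape analysis needs. `morphowrap` implements a
*grid-cast* workflow: a single 2D template grid with stable, row-major
point ids is elastically adjusted to each specimen's outline, then
projected (parallel to the lateral z axis) onto that specimen's 3D surface
mesh. The resulting *casts* are point sets in which the same id marks the
same constructed (semi-landmark) location on every specimen, at a
resolution chosen by the user rather than dictated by anatomy (the default
template is 400 × 320 = 128,000 points).

Downstream, casts support form/shape comparison of two treatment groups:

1. **Superimposition.** Each cast is star-aligned to one prototype
   specimen by the *partial* Procrustes fit (rotation + translation,
   reflections forbidden): size is data here, because overall growth is
   often the dominant biological response. Enabling uniform scaling gives
   the *full* fit, which isolates shape in the narrow sense.
2. **Mean models and displacement fields.** Group means are taken per id
   (an id survives only if valid in every member), the treated mean is fit
   onto the control mean, and per-id coordinate differences give a
   displacement vector field whose magnitudes (Pythagoras, in µm — no step
   of the pipeline ever rescales coordinates) are drawn as heat maps.
3. **Dense inference.** A two-sided Wilcoxon rank-sum test per id *and*
   per coordinate axis (three tests per id, typically >100,000 tests in
   total) with Storey q-value FDR control per axis; plus per-id
   axis-aligned 95% confidence ellipsoids whose overlap/non-overlap
   between groups gives a single three-dimensional verdict per point,
   validated by exchanging 50% of the casts between groups.

## Statistical components

### Rank-sum fields

At every retained id the two groups' coordinates are compared with the
two-sided Mann–Whitney/Wilcoxon rank-sum test. With combined group size
≤ 25 and no ties the exact null distribution is used (`pwilcox`),
otherwise the normal approximation with tie and continuity correction —
the classical `ranksum` behaviour, and study sizes of 10 vs 9 always take
the exact path. The implementation is vectorised over ids (the per-point
loop, not the test, is the workload); base R's `wilcox.test` and a
brute-force enumeration over all rank splits serve as independent oracles
in the test suite.

One calibration subtlety matters when checking Type-I behaviour: the exact
test is discrete. At n = 10 vs 9 the attainable two-sided p-values jump
from 0.00762 to 0.01013, so the probability of `p < 0.01` under the null
is 0.00762, not 0.01. Null-calibration checks in this package therefore
compare the significant fraction against the exact attainable size, not
the nominal threshold.

### Storey q-values

π₀ is estimated on the grid λ = 0, 0.01, …, 0.95 as
`#{p > λ} / (m(1−λ))`, smoothed by a cubic polynomial in λ and evaluated
at λ = 0.95, clipped into (0, 1]. Q-values follow the step-up rule
`q(p_(m)) = π₀ p_(m)`, `q(p_(i)) = min(π₀ m p_(i)/i, q(p_(i+1)))`; fixing
π₀ = 1 reduces the procedure exactly to Benjamini–Hochberg, which the
tests assert to 1e-12. π₁ = 1 − π₀ is reported as a lower bound on the
fraction of truly different points. Multiple testing is controlled within
each axis separately, mirroring how the per-axis maps are read.

### Confidence ellipsoids

Per id and group, the ellipsoid is centred at the mean position with
per-axis radii equal to t-based CI half-widths of the mean,
`t(1−(1−ci)/2, n−1) · s/√n`. Whether the original construction used CIs of
the mean or of the observations is not decidable from the source
description; both differ only by a constant factor, and
`ci_kind = "observation"` exposes the alternative. Ellipsoids are
axis-aligned by construction (no covariance rotation — a deliberate
simplification matching the published construction, not a claim that
coordinates are uncorrelated).

Overlap testing minimises one ellipsoid's quadratic form over the other
ellipsoid. For axis-aligned forms the Lagrange stationarity conditions
decouple per coordinate, leaving a single monotone function of the
multiplier that is bracketed and bisected to 1e-12; touching counts as
overlap, and zero radii degrade gracefully to segments, discs and points
(two distinct points never overlap). Quick accept (centre inside the other
ellipsoid) and quick reject (disjoint bounding slabs) paths decide the
vast majority of ids in practice. A sampling-plus-refinement oracle,
independent of the Lagrange path, confirms the verdicts on hundreds of
random pairs in the tests.

## The synthetic study

Because the package must be testable end to end without imaging data, the
`synthetic` module generates the study conditions directly: two groups of
bilaterally-halved, smooth, convex-ish bodies at millimetre scale. The
control ideal is a half-superellipsoid trunk (default 2400 µm
antero-posterior length, 1600 µm dorso-ventral height, 550 µm lateral
half-width, exponent 2.5) with a tapered, blunt-tipped tail spine
(700 µm × 90 µm base radius). The treated ideal applies a global size
factor 1.1 and a further 1.15 spine elongation — encoding the finding the
workflow is meant to recover: the dominant response is increased size,
with a modest genuine shape change confined to the spine. The elongation
factor is deliberately modest: residual shape displacement under the full
(size-adjusted) fit grows linearly with it (the spine tip sits far from
the centroid, so the least-squares scale is lever-arm weighted), and a
large factor would contradict the "shape change is minor relative to
size" premise the generator encodes.

Casts are produced analytically: the template grid is TPS-warped from the
control body's landmarks (15 named outline points and semi-landmarks:
spine tip/base, head vertex, apices, rostrum, heart indentation, eight
outline points) onto each specimen's landmarks — the synthetic analogue of
the interactive grid adjustment, and the mechanism by which group
differences reach the in-plane coordinates of homologous ids — and the
body's closed-form height field is evaluated at the warped positions. The
mesh + projection route (`make_half_body()` + `wrap_specimen()`) is
exercised separately in tests and agrees with the analytic field away from
the steep silhouette rim; the analytic route keeps the 19-specimen study
fast and its ground truth exact.

Per-individual variation adds, per coordinate axis, a positional noise
field of sd 5 µm composed of a smooth low-order random field (10% of the
variance; spatially correlated biological variation) plus independent
per-point jitter (90%; measurement and projection error), followed by a
random rigid displacement (rotations up to 20°, translations of sd
100 µm) so the Procrustes stage is genuinely exercised. The composition is
a design choice with a statistical motivation: dense rank-sum fields on
*strongly* correlated noise have a significant-fraction whose run-to-run
spread is far wider than binomial, which would make any fixed-seed
calibration check meaningless. With jitter dominating, the null fraction
concentrates near the exact test size. What passing tests therefore do
*not* show: behaviour under strongly spatially correlated biological
variation, non-rigid posture differences, staining/segmentation artefacts
or missing-data patterns of real scans.

The generator's truth is the noiseless displacement field between the two
ideals after the partial fit. Under the default conditions the recovered
field correlates with truth at r > 0.99, the size-adjusted reanalysis
shrinks the median displacement about an order of magnitude, the overlap
map is fully black, and 50% label permutation turns it ≥ 99% purple — the
qualitative signature the workflow is designed to produce.

## Geometry stages and numerical choices

- **Blur.** Separable Gaussian, σ given in µm and converted per axis via
  the anisotropic voxel spacing; mirror-reflected boundaries (no dimming
  of specimens at stack edges; total intensity conserved exactly).
- **Iso-surface.** The volume is first resampled trilinearly onto an
  isotropic lattice (default 15 µm), then triangulated by marching
  tetrahedra: each cube splits into six tetrahedra sharing the main
  diagonal, with linear interpolation along crossing edges. This member of
  the marching-cubes family has no ambiguous configurations, so no lookup
  table and no tie-break policy are needed; output is deterministic and
  vertices are welded so smoothing sees real connectivity. Note that
  iso-surfacing *raw binary* masks places every crossing at an edge
  midpoint and overestimates a sphere's area by ~27%; after the
  workflow's own Gaussian blur the 0.5 level set sits on the true boundary
  and the area error drops below 1%. The area oracles in the tests follow
  the blur-then-extract order for exactly this reason.
- **Smoothing.** Uniform (unweighted 1-ring) Laplacian; passes beyond 3
  warn, since each pass shrinks convex regions.
- **Warping.** 2D thin-plate splines (exact interpolation at λ = 0; the
  linear system is solved in centred unit-scaled coordinates for
  conditioning) or mean-value-coordinate cage deformation; both reproduce
  affine maps exactly and agree to 1e-6 when they encode the same affine
  map.
- **Projection.** Rays are cast along z; per grid point the *maximum-z*
  intersection is kept (the scanned, viewer-side surface of a half body),
  duplicate hits within 1e-9 µm collapse, and points missing the
  silhouette are invalidated — they simply never re-enter any analysis.
- **Missing data.** Every pairwise fit uses the valid-id intersection and
  then transforms all valid points; group statistics use ids valid in
  every cast of both groups, so each test has constant group sizes.

## Problem sizes

The shipped tests and the acceptance script run the full synthetic study
on a 200 × 160 grid (≈19,000 retained ids, ≈57,000 rank-sum tests,
19 specimens), which completes in well under a minute on a single core;
the default 400 × 320 study grid scales all stages linearly in the number
of ids.

## Known limitations

- Axis-aligned ellipsoids understate correlated within-group variation.
- The star alignment depends on the prototype; no iterative
  generalised-Procrustes mean is provided (by design).
- Landmark placement is an input: no automatic landmark detection.
- The permutation validation is qualitative (3 permutations by default),
  not a permutation p-value.
- Allometry (size-dependent shape) is out of scope; export the point
  tables and regress externally if needed.
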