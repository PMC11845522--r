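---
title: "Methods: rigid inner-ear normalization and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rigid inner-ear normalization and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labnorm)
```

This vignette explains the models and procedures implemented in `labnorm`,
the parameters that matter, the design decisions that were genuinely open,
and what the synthetic phantom validation does and does not show about real
data.

## Coordinate conventions

All geometry lives in a right-handed, RAS-like physical space measured in
mm: the first axis is left–right, the second posterior–anterior, the third
inferior–superior. A `lab_volume` maps the 0-based voxel index `(i, j, k)`
(voxel centers) to `origin + direction %*% (spacing * c(i, j, k))`, with an
orthonormal `direction` matrix; oblique or sheared grids are rejected at
the NIfTI boundary. Scanner exports differ in which convention their
headers encode (LPS vs RAS); rather than guessing an acquisition
convention, the package fixes this one and applies it consistently, which
is all that rigid registration requires.

A `rigid_transform` maps *moving*-space physical points into *fixed*
(atlas)-space physical points as `y = R (x − c) + c + t` with `det(R) = +1`
enforced at construction; resampling evaluates the inverse map on the
reference grid. Mirroring of left-ear data is an index flip about the
grid-center sagittal plane — geometry untouched, therefore an exact
involution — plus `mirror_point()` so landmark coordinates can follow.

## Preprocessing

`crop_roi()` keeps spacing and direction and shifts the origin so every
retained voxel keeps its physical position. `upsample_2x()` doubles every
axis with separable tricubic Catmull–Rom interpolation (`a = −0.5`):
although the workflow it reproduces used a slice-based "bicubic" tool, 2D
upsampling would leave the through-plane axis nearest-neighbour, which
contradicts an isotropic two-fold rescale, so the kernel is applied along
all three axes. The output convention is exactly `2n` voxels per axis with
new centers at quarter-spacing offsets around the old ones (the common
image-rescaling convention), halved spacing, replicate padding at the
boundary. Catmull–Rom reproduces polynomials up to degree one, which the
tests exploit as an exact oracle on linear ramps.

Whether to crop before or after upsampling is not fixed by the method; the
command-line front end composes the steps in any order and defaults to
crop → upsample → mirror, which minimizes memory.

## The 3P landmark registration

Three fiducials — the most lateral point of the posterior semicircular
canal, the most superior point of the superior canal, the cochlear apex —
give a closed-form least-squares rigid fit (centroid alignment, SVD of the
3×3 cross-covariance, determinant-sign correction). No iterative optimizer
and no scale factor: with exactly three non-collinear points the proper
rigid minimizer is unique, and admitting scale would defeat the purpose of
geometry preservation.

Two numerical points. First, three centered points are always coplanar, so
the smallest singular value of the cross-covariance is ~0 and the sign of
the third singular vector is arbitrary; the determinant correction handles
this silently. A *reflective* correspondence warning is only meaningful
when the third singular value is materially positive, which cannot happen
with three points (the mirror image of a planar triplet is reachable by
flipping the plane over — a proper rotation). Second, collinear triplets
leave the rotation about the common line free, so they are rejected at
construction (triangle area ≤ 1e-6 mm²).

The fiducial registration error (RMS residual at the landmarks, mm) is
always computed; fits above a configurable 2 mm threshold warn but are not
rejected — a quality flag, not a gate, since a human operator reviews
semi-manual registrations anyway.

## The intensity registration engine

One engine serves the mask-aided method and both unmasked baselines; the
presets differ only in the mask and minor optimizer constants, because the
performance difference of interest is attributable to the mask, not to
tool-specific optimizer tuning. No per-dataset hyper-parameter tuning is
done anywhere.

* **Metric.** Mattes-style mutual information: intensities are linearly
  binned (32 bins per channel) with partial-volume weighting into a joint
  histogram, MI in nats. Samples are drawn once per pyramid level
  (seeded, default 25% of the metric region, floor of 1000) from the fixed
  image — only inside the fixed mask when one is set. Fixed sampling makes
  the metric deterministic and smooth enough for a simplex optimizer.
* **Pyramid.** Three levels, shrink 4/2/1 with Gaussian smoothing
  2/1/0 mm. Block-mean downsampling keeps the geometry exact (block
  centroids become the new voxel centers).
* **Initialization.** Geometric-center alignment, then an exhaustive
  coarse sweep at the coarsest level: Euler-angle grid (±15°, 7 steps per
  axis) and a translation grid (±6 mm, 7 steps). The sweep bests join the
  center start as *candidates* rather than replacing it.
* **Optimization.** Per level, Nelder–Mead with restarts: a fresh simplex
  at the incumbent until a restart no longer improves the metric (up to
  6). NM in 6 dimensions is prone to premature simplex collapse; restarts
  are the standard cure and keep the engine derivative-free. The candidate
  set is carried in parallel through the coarse levels and reduced to the
  single best at the second-finest level — one misleading coarse basin
  (e.g. background texture alignment) then cannot capture the search.
* **Non-convergence.** Never an exception: the result carries
  `converged = FALSE` when the iteration cap is hit at the finest level
  without a plateau, or when the final transform violates sanity bounds
  (rotation > 45° or translation drift beyond half the fixed field of
  view). This mirrors how registration failure is a *recorded outcome* in
  rating studies, not a crash.

The TIE mask is the atlas binarized (Otsu by default) and dilated with a
Euclidean ball. The dilation radius is specified in voxels — 10 voxels on
the 0.25 mm working grid of upsampled data, i.e. a 2.5 mm margin; on a
0.5 mm grid the equivalent margin is 5 voxels, which is what the demo
pipeline uses. Dilation is computed by FFT convolution with the exact
lattice ball (verified against brute-force enumeration), so masks are
identical to a direct morphological dilation.

## Group evaluation

`median_volume()` is the voxelwise median over co-registered volumes (even
counts: mean of the central order statistics — the rule must be total even
though typical cohorts are odd-sized). The colocalization battery against
the atlas is always ROI-masked, because background voxels otherwise
dominate every coefficient:

* **Costes auto-threshold.** Orthogonal (total-least-squares) regression
  `ch2 ≈ a·ch1 + b` over the ROI fixes the line along which the candidate
  threshold pair `(T, aT + b)` moves; `T` sweeps downward through the
  *distinct observed* ch1 intensities (data-adaptive and exactly
  reproducible, unlike a fixed step) and stops at the largest `T` whose
  below-both-thresholds Pearson correlation is ≤ 0. If even the full ROI
  correlates non-positively the thresholds are set to the channel maxima
  and flagged. For `a ≥ 0` the below-threshold subset shrinks
  monotonically as `T` falls, so the sweep runs incrementally in
  O(n log n); the tests pin it to a brute-force oracle sweep.
* **Manders split.** `tM1` = fraction of ch1 intensity where ch2 exceeds
  its threshold, and symmetrically `tM2`; negative intensities are clipped
  to zero for the sums (with a message).
* **Correlation and fit.** Pearson on raw intensities, Spearman as Pearson
  on average ranks, and an OLS fit of the registered volume on the atlas
  (slope near 1 = ideal). Whether the original plugin computed Spearman
  before or after thresholding is unknowable from its output; it is
  computed over the full ROI here, and both Pearson and Spearman are
  surfaced to remove the ambiguity.

## Rating statistics

Grades live on the 6-point school scale with half-steps (1 = best, 6 = no
alignment/non-convergence). "Insufficient" means grade ≥ 5, half-steps
included (5.5 lies between the two named failing grades); the cutoff is an
argument. The ANOVA defaults to per-dataset mean grades across raters as
observations — with 153 datasets and 4 methods this yields the
612-observation, `df_within = 608` layout of the published analysis — with
fully pooled ratings as the documented alternative. Cohen's d divides the
pairwise mean difference by the ANOVA-pooled SD (root of the within-group
mean square; for equal group sizes the root of the average group
variance). This is the only convention that reproduces the published
effect sizes from the published group moments (e.g. 1.28 / 1.0495 = 1.22),
so it is the default. Bonferroni multiplies by the number of pairwise
comparisons, capped at 1. Grades are treated as interval data throughout,
matching the source analysis; an ordinal-regression alternative is out of
scope and noted as a caveat.

Inter-rater agreement is rank-based by design: raters grade around
different personal baselines, which rank correlation ignores and a
chance-corrected kappa would punish. Spearman's rho uses average ranks;
Kendall's tau-b adds tie correction, which matters on a 6-point scale.
Both come with asymptotic p-values.

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes an analytic labyrinth: three partial torus
canals with near-orthogonal plane normals (pairwise 90° ± 20° enforced), a
vestibule ellipsoid, and a conical-spiral cochlear tube, rasterized by
signed distance at voxel centers with a half-voxel soft edge (hard
voxelization would alias and make MI registration artificially easy or
unstable). The fluid is bright (100) on darker tissue (10), Gaussian
blurred (0.3 mm) with seeded additive Gaussian noise (SD 2; Rician
optional — at this SNR magnitude-MRI noise is near-Gaussian). Truth
landmarks (canal extremes, cochlear apex) are computed analytically and
transformed by the same pose as the geometry, so registration error can be
measured against exact ground truth; `phantom_atlas()` plays the fixed
atlas: identity pose, no noise.

Two features exist specifically to reproduce the failure mechanism that
motivates masking:

* a **distractor** — a large bright ball at the far corner of the crop
  (brainstem-like), present in the atlas at its canonical position but
  displaced independently of the labyrinth pose in each subject, so its
  own best alignment conflicts with the labyrinth's. It is deliberately
  clear of the labyrinth and its 2.5 mm mask margin; anatomically the
  brainstem does not touch the inner ear, and a distractor inside the
  masked region would degrade every method alike.
* a **background texture** — a fixed sum of incommensurate 3D sinusoids
  under an 8 mm Gaussian envelope around the labyrinth, moving rigidly
  with it, like the petrous-bone pattern around a real inner ear. Without
  it the atlas background is perfectly flat and rank correlations over the
  ROI are noise-dominated; without the envelope the quasi-periodic pattern
  admits false registration optima a wavelength away.

Cohorts jitter pose (uniform ±10° / ±4 mm by default), canal radii
(multiplicative, SD 6%) and canal-plane tilt (SD 4°); subject k draws from
a named substream of the master seed, so cohorts are reproducible and
different seeds share no noise. Real inter-subject orientation variability
is not quantified in the literature this emulates; the defaults are stated
here as configuration, not as measured anatomy.

What passing phantom tests does **not** show: the phantom has no bone/air
interfaces, no intensity inhomogeneity, no partial-volume-specific
artifacts, no pathology, and its "anatomy" differs between subjects far
more regularly than real labyrinths do. Results on phantoms bound the
best case of each method under a known ground truth; they do not predict
absolute accuracy on patient data.

## Problem sizes and tolerances

The shipped tests and the acceptance script run on 48³ grids at 0.5 mm
(24 mm field of view) with 12-subject demo cohorts — sizes chosen so the
whole suite completes in a few minutes on one CPU while every structure
spans multiple voxels. At this size, with poses to ±15° / ±5 mm, the
masked registration recovers 20/20 seeded poses to ≤ 0.5° / 0.25 mm. The
supported envelope is grids of ≥ 48³ at 0.5 mm (or equivalent field of
view) under the default jitter: on a 40³ crop the posed labyrinth reaches
the crop edge, partial mask overlap makes the MI optimum unreliable, and
the engine reports non-convergence or a wrong basin — the same behaviour
rating studies record as failed registrations on tightly cropped data.

Key numeric tolerances: direction-matrix orthonormality 1e-9 (header
round-trips are float32, so NIfTI geometry reproduces to ~1e-6);
landmark-fit exactness on noiseless correspondences is at machine
precision (measured ≤ 1e-12 mm over 100 random poses); rotation angles are
measured with the atan2 form, which is well-conditioned near 0 where the
acos-of-trace form loses half the available digits; mask-volume stability
under pose is asserted at 2% on a 0.25 mm grid, the rasterization
quantization floor for the thin canal tubes.

## Known limitations

* The registration engine is deliberately derivative-free and
  single-threaded; it is built for small crops (tens of mm), not
  whole-head volumes.
* Oblique acquisition grids are rejected rather than resampled; bring data
  to an orthonormal grid first.
* The Costes sweep's incremental path assumes a non-negative orthogonal
  slope; anticorrelated channels take the (slower) direct path and are
  flagged.
* Inter-observer landmark placement noise is not simulated by default
  (`landmark_noise_mm` exposes it); the 3P results on phantoms therefore
  represent a single ideal operator.
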