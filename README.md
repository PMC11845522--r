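# labnorm

Geometry-preserving spatial normalization of multisubject inner-ear 3D MRI.

## The problem

Group-level analysis of inner-ear imaging (semicircular canals, vestibule,
cochlea) needs every subject's volume in one shared atlas coordinate
system. Because petrous-bone geometry is itself the object of study, only
**rigid** registration — rotation plus translation, no scaling, shearing or
warping — is admissible. But the labyrinth is tiny relative to everything
else in the crop: an unassisted intensity-based registration samples mostly
background and large bright structures (e.g. brainstem), so the optimizer
happily aligns those and leaves the inner ear misplaced.

`labnorm` implements and compares four rigid normalization strategies for
researchers working with high-resolution T2 inner-ear crops:

* **3P** — semi-manual: a closed-form least-squares rigid fit from three
  anatomical fiducials (lateral pole of the posterior semicircular canal,
  superior apex of the superior canal, cochlear apex). For paired point
  sets `P, Q` the rotation is `R = U S Vᵀ` from the SVD of the centered
  cross-covariance `H = (Q−q̄)(P−p̄)ᵀ`, with `S = diag(1, 1, det(UVᵀ))`
  forbidding reflections; the fiducial registration error (RMS residual,
  mm) is always reported.
* **TIE** ("thick inner ear") — automatic: rigid mutual-information
  registration whose metric samples are restricted to an atlas-derived
  inner-ear mask, volumetrically dilated by a Euclidean ball (default 10
  voxels ≙ 2.5 mm at the 0.25 mm working resolution).
* **ANTs-like / Elastix-like** — the unmasked baselines, same engine and
  Mattes-style MI metric (32 bins, fractional random sampling, 3-level
  coarse-to-fine pyramid, geometric-center initialization), no mask.

Around the registration core the package provides the full evaluation
machinery: voxelwise **median group volumes**; ROI-masked **colocalization
analysis** against the atlas (Costes auto-threshold, thresholded Manders
split coefficients tM1/tM2, Pearson/Spearman correlation, OLS scatter fit);
**Likert rating statistics** (per-method summaries, insufficiency rates,
one-way ANOVA with Bonferroni post-hoc tests and pooled-SD Cohen's d,
Welch's t, pairwise inter-rater Spearman rho and Kendall tau-b); and a
**synthetic labyrinth phantom** generator (analytic signed-distance
geometry: three near-orthogonal canal tori, vestibule ellipsoid, conical
cochlear spiral; rigid pose jitter, anatomy jitter, noise, and an optional
bright brainstem-like distractor) so the whole pipeline can be validated
end-to-end without patient data.

## Worked example

Twelve phantom subjects with jittered pose and anatomy plus a distractor,
registered to the phantom atlas by all four methods, median volumes
compared to the atlas within the dilated inner-ear ROI:

```r
library(labnorm)
run <- run_pipeline(pipeline_config(n_subjects = 12, distractor = TRUE,
                                    seed = 17))
print(run)
#> <pipeline_run> 12 subjects, methods: 3p, tie, ants-like, elastix-like
#>   3p           TRE 0.121 mm (median 0.118), converged 12/12, rho 0.941
#>   tie          TRE 0.201 mm (median 0.203), converged 11/12, rho 0.942
#>   ants-like    TRE 1.389 mm (median 0.853), converged 10/12, rho 0.915
#>   elastix-like TRE 1.000 mm (median 0.638), converged 11/12, rho 0.915
```

TRE is the target registration error at the three fiducials (mm, against
the known generating pose); `rho` is the Spearman correlation between each
method's median volume and the atlas inside the ROI. The mask-aided and
landmark methods keep the labyrinth sub-voxel accurate while the unmasked
baselines drift toward the distractor, and their group medians correlate
correspondingly worse — the rank ordering the rating study found on real
data.

Single steps are plain functions on `lab_volume` objects:

```r
atlas  <- read_volume("atlas.nii.gz")
mask   <- make_tie_mask(atlas, "otsu", dilation_radius_voxels = 10)
moving <- read_volume("sub01.nii.gz")
res    <- register_rigid(moving, atlas,
                         registration_config("tie", fixed_mask = mask,
                                             random_seed = 1))
reg    <- resample_linear(moving, res$transform, atlas)
coloc_analysis(reg, atlas, mask)
```

A thin command-line front end mirrors these functions
(`Rscript inst/cli/labnorm.R <phantom|preprocess|register-3p|register|median|coloc|rate-stats|run> --help`).

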