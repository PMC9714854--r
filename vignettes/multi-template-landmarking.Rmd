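---
title: "Multi-template automated landmarking: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-template automated landmarking: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Geometric morphometrics quantifies the shape of biological structures by
ordered sets of anatomical landmarks. Placing landmarks by hand on hundreds of
3D surface models is slow and introduces intra- and inter-observer error.
Registration-based automation transfers the landmarks of a manually annotated
*template* specimen onto unlabeled *targets*, but a single template biases the
estimates wherever a target's form differs strongly from the template — the
usual situation in multi-strain or multi-species samples.

This package implements the multi-template strategy: several templates are
registered to each target independently, each proposes a full landmark set,
and the final estimate of every coordinate is the **median across templates**.
The median, unlike the mean, is insensitive to the occasional template whose
registration fails outright, so a target is effectively landmarked by
whichever templates happen to suit it. Templates are chosen by K-means
clustering in a morphospace built from correspondent point clouds, and a
post-hoc quality check flags per-template estimates that stray too far from
the fused output.

## Pipeline and models

### Single-template transfer

`alpaca_single()` performs one template-to-target transfer:

1. Both meshes are subsampled to sparse clouds by a greedy minimum-spacing
   rule (`subsample_by_spacing()`): vertices are scanned in order and kept iff
   they lie at least `spacing` mm from every kept point. Deterministic; the
   spacing is tuned by bisection (`tune_spacing()`) so the template cloud has
   about `target_points` points (default 250 at the package's desk-scale
   defaults).
2. The template cloud is rigidly aligned to the target cloud
   (`global_rigid_align()`): FPFH-style local descriptors (11 bins per Darboux
   angle; normal radius 2x spacing, feature radius 5x spacing) are matched,
   and a similarity transform (scale clamped to [0.2, 5]) is fitted by RANSAC
   over 4-point correspondence samples with an inlier threshold of 1.5x
   spacing. Because descriptor matches can be pose-ambiguous for
   near-symmetric shapes, the RANSAC stage is restarted three times and four
   principal-axes alignment hypotheses are added; all candidates are scored by
   nearest-neighbor RMS after a 10-iteration ICP polish and the best fit wins.
   Full point-to-point ICP (`icp_refine()`) then refines the winner; its
   objective is monotone non-increasing.
3. The aligned template cloud is deformably registered to the target cloud by
   coherent point drift (`cpd_deformable()`): an EM fit of a Gaussian-kernel
   displacement field `v(x) = sum_m w_m exp(-||x - y_m||^2 / (2 beta^2))` with
   motion-coherence regularization `lambda` and an explicit outlier mixture
   weight `w_outlier`. Clouds are internally rescaled so the target
   bounding-box diagonal is 25 units, which makes `beta` and `lambda`
   transferable across specimen sizes; the defaults `beta = 2`, `lambda = 2`,
   `w_outlier = 0.1`, at most 150 EM iterations with relative tolerance 1e-5
   on the noise variance, follow the cloud-scaled conventions of the
   point-cloud landmarking tools this package is modeled on. The variance is
   floored at 1e-10 and the M-step system carries a 1e-9 ridge; both only
   matter when the fit is essentially perfect.
4. The template landmarks are pushed through the fitted displacement field
   (`warp_points()`). Optionally (`project_to_surface`) each estimate is
   snapped to the closest point on the target's triangle surface; the default
   reports the raw warped positions, since snapping is a presentation choice
   that can hide registration error.

Estimates are always expressed in the target's own coordinate frame — the
target mesh is never moved.

### Median fusion

`run_malpaca()` runs every (template, target) pair independently (all runs use
the same seed, so a pair gives the same answer alone or in a batch) and
`median_aggregate()` fuses each target's T x L x 3 estimate stack
coordinate-wise. For even T the median is the midpoint of the two central
values. A failed registration leaves an all-NA slice that is excluded from the
median and recorded in the run manifest — never zero-filled. The full stack is
kept (and written to disk) because it is the raw material for quality control.

### Template selection

`select_templates()` builds the selection morphospace in three steps:
correspondent clouds (`build_correspondent_clouds()`: the first specimen's
subsampled cloud is rigidly registered to every other specimen and each point
replaced by the closest vertex of that specimen — row i corresponds across the
whole sample), generalized Procrustes analysis (`gpa()`), and PCA of the shape
coordinates (`pca_shape()`). K-means (Lloyd's algorithm via `stats::kmeans`,
10 random restarts under a fixed seed) partitions the full, unstandardized PC
score matrix into k clusters, and the specimen nearest each cluster centroid
(full-dimensional distance, ties to the lowest index) becomes a template.
`select_templates_grouped()` repeats the whole procedure inside each
a-priori group, as one would per species. `stats::kmeans` has Lloyd
iterations but no k-means++ seeding, so restarts rather than seeded
initialization guard against poor local optima.

GPA here is the classical iterative superimposition: center, scale to unit
centroid size (optional but default; centroid sizes are recorded beforehand
either way), rotate to the running mean by rotation-only orthogonal Procrustes
(determinant-corrected SVD — anatomical shapes must not be mirrored), repeat
until the mean changes by less than 1e-10. The final orientation is
canonicalized to the mean shape's principal axes with signs fixed by third
moments, so GPA output is invariant to the specimens' original poses, not just
equal up to rotation.

### Evaluation and the permutation test

`rmse()` is the per-specimen root-mean-square Euclidean deviation over
landmarks; `rmse_report()` also scales it by the reference set's centroid
size. `welch_t_one_sided()` wraps Welch's unequal-variance t test for
comparing error distributions. `correlation_report()` runs separate GPAs on
the estimated and reference families and correlates centroid sizes, pairwise
Procrustes distances, and the first six PC scores (each estimated PC against
each reference PC; absolute values are reported alongside signed ones because
PC signs are arbitrary).

`permutation_template_test()` asks whether a chosen template set beats chance:
it draws random k-subsets as templates, runs the full multi-template transfer
for each, and reports the rank fraction — the share of random sets with a
strictly smaller mean RMSE. The focal combination is not excluded from the
sample space (an unbiased null), and since transfers are deterministic per
pair, recurring (template, target) pairs are computed once and reused.

### Post-hoc quality control

`detect_outliers()` measures, for one target, each template estimate's
distance to the fused median, pools the T x L distances, and flags strict
exceedances of `mean + 2 sd` (sample sd, divisor TL − 1 — the package's
choice for small T, recorded in the mask's metadata; the multiplier is
exposed). The threshold is strictly per-specimen. `recompute_median_excluding()`
re-fuses without the flagged estimates; `subset_fusion()` restricts fusion to
named templates (e.g. only the target's own species). A useful consequence of
the pooled rule: with a T-template stack, a *wholesale* corrupted slice is
detectable only for T ≥ 6 (for smaller T the corrupted values inflate the sd
past their own distance), whereas a single stray estimate is flagged already
at T = 3.

## The synthetic test bed

No real scan collection ships with the package; all validation runs on
generated populations whose ground truth is exact.

`make_base_shape()` builds a closed "skull-like" surface: an icosphere
(subdivision 3, 642 vertices by default) stretched to a 3 x 2 x 1.5 mm
ellipsoid, given an egg-like taper along +x, a fixed anterior "snout" bump, a
dorsal "vault" bump and a parabolic dorsal arch, plus `n_bumps` seeded random
bumps. The fixed asymmetries are deliberately strong: like a real skull — and
unlike a plain ellipsoid — the shape has no approximate 180-degree symmetry,
so its pose is geometrically identifiable by registration. Landmarks (16 by
default) are the apex vertices of the random bumps plus the six axis-extremal
vertices; they are exact mesh vertices and remain mathematically tied to the
surface through every later deformation.

`apply_smooth_warp()` deforms vertices and landmarks identically through an
analytic Gaussian radial-basis field, refusing warps whose Lipschitz bound
reaches 1 (fold risk) or whose amplitude exceeds 15% of the diameter.
`make_population()` composes, per specimen: a group-mean warp (3 centers,
width 1.8 mm, amplitude 0.9 mm — about 12% of the object, i.e. species-scale
differences), an individual warp (4 centers, width 1.2 mm, amplitude 0.15 mm,
about 2%, individual-scale), a random rigid pose and a uniform scale drawn
from [0.9, 1.1]. The 6x amplitude ratio realizes a clearly grouped sample
once the ~0.1–0.2 mm quantization noise of closest-vertex correspondence is
accounted for. `corrupt_template_slice()` displaces one template's estimates
by fixed-length random offsets, emulating a grossly misregistered template.

What the generator does *not* emulate: scanning artifacts (holes, spikes,
disconnected components), landmark placement noise in the templates
(template landmarks are exact), strongly allometric size–shape coupling, and
anatomical detail at scales below the bump width. Passing tests therefore
demonstrate the pipeline's correctness and its robustness to smooth shape
variation, pose, scale, and gross registration failure — not its accuracy on
noisy real scans.

## Default problem sizes

The package's defaults are a desk-scale mirror of a realistic study: 12
specimens in 3 groups, 16 landmarks, 642-vertex meshes, ~250-point clouds,
k = 3 templates, 20 permutations in the permutation test. These sizes keep a
full pipeline run in minutes while preserving the ratios that matter
(templates ≈ 10–25% of the sample, clouds much sparser than meshes). Every
stochastic step takes an explicit seed, and the command-line interface
(`malpaca_cli()`, wrapper script in `inst/cli/`) reruns byte-identically for
identical seeds.

## Numerical choices and degenerate inputs

* Subsampling keeps the *first* point of any conflicting pair (vertex order),
  making clouds reproducible without randomness; ties in nearest-vertex
  queries go to the lowest index.
* A subsample that would leave fewer than 3 points errors out — unless the
  input itself had fewer than 3 points, in which case the greedy rule's output
  is returned as-is (the degenerate input was the caller's choice).
* `kmeans_select()` refuses an all-identical score matrix (selection would be
  meaningless) and retries with fresh restarts if Lloyd's algorithm empties a
  cluster; `k = K` short-circuits to "every specimen its own template".
* Collinear correspondence sets make the similarity fit singular; this is
  detected via the second singular value and reported as degenerate geometry.
* FCSV files without a coordinate-system header are read as RAS; LPS inputs
  (FCSV or markups JSON) are converted by negating x and y. All internal
  coordinates are RAS millimeters. Markups JSON is written in LPS, as the
  Slicer ecosystem does; FCSV and CSV are written in RAS with an explicit
  header.
* Mesh writing is binary little-endian PLY with double-precision coordinates,
  so write-read round-trips are exact; ASCII PLY, OBJ, STL and legacy VTK
  polydata are read-only inputs.

## Known limitations

* Closest-point correspondence targets mesh vertices, so its resolution is
  bounded by vertex density; on very coarse meshes the quantization noise can
  rival small individual shape differences.
* The reference specimen seeds the correspondence; a different reference
  yields slightly different clouds and possibly a different template set. The
  reference index is exposed, and no invariance is claimed.
* The number of templates k is a user choice; the package provides no rule
  for it.
* Rigid alignment assumes the two shapes share gross geometry; samples mixing
  anatomically different structures (or models with large extraneous parts)
  violate the method's assumptions and are the user's responsibility to
  curate.
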