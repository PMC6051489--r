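---
title: "Patch-to-volume reconstruction: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-to-volume reconstruction: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fast 2D MRI sequences (ssFSE and relatives) acquire sharp single slices,
but a 3D stack of such slices is corrupted by motion occurring *between*
slice acquisitions: fetal movement, maternal breathing, bowel motion.
Classical slice-to-volume registration (SVR) restores a consistent 3D
volume by rigidly registering each whole slice to an iteratively refined
high-resolution (HR) reconstruction — which presumes everything on a
slice moves rigidly together. That assumption holds for a masked fetal
brain and fails for large fields of view containing independently moving
parts (head vs. trunk vs. placenta).

Patch-to-volume reconstruction (PVR) relaxes the rigidity assumption to
patch scale: every acquired slice is decomposed into overlapping patches
(squares, or dilated SLIC superpixels), each patch is registered rigidly
on its own, and an expectation-maximization (EM) inlier/outlier mixture
down-weights or rejects data that no rigid patch pose can explain. The
package implements the full loop plus a synthetic-motion evaluation
harness and image-quality metrics.

## Forward model

Each low-resolution (LR) pixel is modelled as a PSF-weighted average of
HR voxels:

* acquisition: `Y_i = D B T_i X + n_i`, with `T_i` rigid motion, `B` the
  PSF blur, `D` slice sub-sampling;
* simulation: for pixel `j` of patch `s`, `y*_j = Σ_v w_jv x_v` with
  footprint weights `w_jv` obtained by evaluating the PSF at the offset
  between the transformed pixel centre and voxel `v`, expressed in the
  slice frame, then normalized to sum 1.

The PSF is separable: in-plane a truncated-Taylor series of
`sinc(x) = 1 − x²/3! + x⁴/5! − ...` with its first zero at the in-plane
spacing, windowed by a Gaussian whose FWHM is twice the in-plane spacing
(so the main lobe survives and far side lobes vanish); through-plane a
Gaussian slice profile with FWHM equal to the slice thickness. The true
ssFSE slice profile is scanner-specific and not available, so the
Gaussian surrogate — standard in this literature — is used and stated as
such. Negative sinc lobes are clipped to zero before normalization so
every footprint is a convex combination; this gives the forward operator
a maximum principle (a simulated pixel can never exceed the range of the
voxels it observes).

The number of retained Taylor terms is derived from the requested
relative error bound `epsilon` (default `1e-6`): the alternating-series
remainder is bounded by the first omitted term, and the term count is
chosen so that bound holds at the support edge. At the default support
radius (twice the largest voxel extent, 5 mm for 1.25 × 1.25 × 2.5 mm
acquisitions) this yields 21 terms. A fixed small term count cannot meet
a `1e-6` bound at `x = 4π`, which is why the count follows `epsilon`
rather than being a constant.

## Reconstruction loop

1. **Template selection** — the stack with the highest mean normalized
   cross-correlation between consecutive slices (through-plane
   inconsistency is the motion proxy); deterministic tie-break to the
   lowest index, user override allowed.
2. **Intensity matching** — every stack is rescaled by a single gain so
   its foreground median matches the template's. Gain-only matching
   preserves the zero background.
3. **3D-3D initialization** — each stack is rigidly registered to the
   template (cross-correlation, 3-level pyramid, coordinate descent;
   translation-only at the coarsest level, where rotations are poorly
   constrained).
4. Per scale, per outer iteration:
   a. **patch extraction** (squares `a`/stride `ω`, or SLIC superpixels
      of step `a` dilated by `γ`), transforms initialized from the
      parent stack's transform re-centred on the patch centroid;
   b. **patch-to-volume registration** against the frozen current
      volume;
   c. **EM outlier classification** on the residuals `y − y*`;
   d. **super-resolution**: several preconditioned gradient-descent
      steps on
      `Σ_s p̂_s Σ_j p_j (y_j − y*_j)² + λ R(X)`.

The SVR baseline is the same loop with one whole-slice patch per slice.

## Regularization

`R(X)` averages the edge-preserving penalty
`phi(t) = 2√(1+t²) − 2` over the 26-neighbourhood:
`R(X) = (1/26) Σ_i Σ_d phi((x_{i+d} − x_i)/(δ|d|))`. `δ` (default 150,
intensity units; useful range roughly 100–400 for data scaled to
[0, 1000]) sets the gradient magnitude treated as an edge: below it the
penalty is quadratic (smoothing), above it linear (edge-preserving).
`λ` starts at `0.8 δ²` and is halved after every outer iteration.

Two normalization conventions exist for neighbourhood regularizers: sum
over directions or average over them. With the sum, the `0.8 δ²`
starting weight lets the regularizer overwhelm the data term roughly
26-fold and the volume drifts toward flatness; with the direction
average the two terms are balanced and the stated `λ` schedule behaves
as intended. The package uses the average. The gradient step is
preconditioned by the per-voxel curvature estimate
`2 · confidence + λ R''` and step sizes are chosen by backtracking
(halving from 1, at most 8 times); a step that cannot decrease the
objective is rejected and flagged. Voxels observed by no patch receive
no data-term update; the regularizer may still relax them toward their
neighbours, which acts as inpainting of coverage gaps.

The initial volume is the confidence-weighted PSF scatter of all patch
intensities under the stack-level transforms; uncovered voxels take the
foreground median. Output intensities are clamped to the observed input
range only on the final volume, never during descent.

## Patch registration

The similarity is cross-correlation (CC) between patch intensities and
the volume evaluated at the rigidly transformed pixel centres. Two
search profiles:

* `fast` (pipeline default): bounded greedy coordinate descent over a
  blurred-volume pyramid, warm-started from the patch's current
  transform, search bounded to ±3°/±3 mm per outer iteration, and a new
  pose is only accepted if CC improves by at least `1e-3`. Inside the
  loop, motion increments between iterations are small; the bound and
  the acceptance margin prevent slow drift of ambiguous patches against
  a still-blurry intermediate volume.
* `robust`: 25 short Nelder-Mead starts on a grid of out-of-plane
  rotation offsets (the weakest-identifiability directions for a flat
  2D patch), a long refinement plus one simplex re-inflation, a
  coordinate polish, and finally a polish under the full PSF-simulated
  objective. The last stage matters because acquired pixels are
  thick-slice averages: an interpolated objective carries a small
  out-of-plane bias (of order 1°) that the simulated objective does
  not. This profile attains the intended ±5°/±5 mm capture range at
  roughly ten times the cost of `fast`.

Patches with near-zero intensity variance or with less than 30%
foreground pixels are not registered (their rigid pose is ambiguous —
a patch of air slides freely); they keep the stack-level transform and
still contribute to the data term. Candidate poses leaving less than
half the patch in-field are inadmissible.

## EM outlier model

Residuals are modelled as a zero-mean Gaussian (inliers, variance `σ²`,
proportion `c`) plus a uniform density `m = 1/(max e − min e)`
(outliers). Per-voxel posteriors `p` enter SR as continuous weights;
the patch posterior `p̂ = √(Σp²/N)` drives a binary exclusion at
`p̂ < 0.5`. Excluded patches keep being re-registered and re-scored, so
they can re-enter. Initialization is `c = 0.9`, `σ²` the residual
variance.

`em_update()` iterates to convergence and is the right tool for a
standalone mixture fit. Inside the reconstruction, one EM update per
outer iteration is performed, with the mixture state carried across
iterations. The reason is a degeneracy of noise-free residual
distributions: they are sharply peaked at zero with heavy structured
tails (edges), and a fully converged fit collapses `σ` onto the flat
regions, classifying every edge as an outlier and erasing exactly the
structure SR is meant to recover. One update per iteration tracks the
shrinking residual scale at the pace the reconstruction itself improves,
which is how interleaved robust-statistics reconstruction is normally
run.

The rigidity map projects `p · p̂` into the HR grid with the same
normalized PSF weights used for reconstruction: values near 1 mark
regions whose motion was consistent with the rigid patch model, and the
map doubles as an uncertainty visualization and a candidate mask for a
subsequent SVR refinement of rigid subregions.

## The synthetic study

`make_phantom()` builds a deterministic brain-like volume: an outer
ellipsoid with a bright fluid rim, a cortical band, two deliberately
asymmetric ventricle-like inclusions, a dark frontal wedge, 24 seeded
sharp blobs, and fine multiplicative texture (correlation length about
3 mm, 12% amplitude). The asymmetries and texture are not decoration:
a rotationally symmetric phantom makes rigid registration
unidentifiable, and the texture supplies the features patch-scale
registration locks onto. Intensities live in [0, 1000], which pairs
with the default `δ = 150`.

`apply_motion()` implements three corruptions: whole-volume translation
along x; bulk rotation of the upper half about z (split at the axial
mid-plane, boundary slice assigned to the moved half); and a combined
skew with all six off-diagonal shear entries equal to `tan(θ)`, applied
about the volume centre and refused for |θ| ≥ 45°.

`sample_interleaved_stack()` emulates acquisition: slices alternate
between the motion-free and the corrupted volume (even slice indices
free, odd corrupted, configurable), on an anisotropic grid
(1.25 × 1.25 × 2.5 mm by default) in axial/sagittal/coronal
orientation. By default each slice integrates a Gaussian slice profile
(FWHM = slice thickness, five taps) through-plane. This matters: the
reconstruction's forward model says LR = PSF(HR), and point-sampled
slices contradict it — super-resolving point samples with a blur model
over-sharpens. Point sampling remains available as an option.

What the harness does *not* emulate: acquisition noise, bias fields,
k-space artifacts, spin physics, or continuous (intra-slice) motion.
Passing tests on this phantom therefore demonstrate the geometric and
statistical machinery — forward model, registration, robust weighting,
super-resolution — not robustness to scanner noise or intensity
inhomogeneity, which on real data are handled upstream or by the EM
weights.

## Default experiment sizes

The bundled experiments are desk-scale by design: a 96 mm (96³ voxel)
phantom with three interleaved stacks for the skew comparison, a 64³
phantom for the bulk-rotation rigidity experiment, a 1.25 mm isotropic
target grid, fixed-scale variants run 2 outer iterations with 7 SR
steps each, and the multi-scale superpixel schedule is
`a = 16, 24, 36, 54` (factor 1.5, 2 iterations per scale). A superpixel
step at or beyond the slice size degenerates gracefully to one
whole-slice segment. The published multi-scale description ("up to 40")
is consistent with either capping the last scale or rounding; the
uncapped geometric schedule is used here and is configurable.

## Numerical choices and degenerate inputs

* Footprints used inside the pipeline prune weights below 1% of the
  per-pixel maximum (then renormalize): a ~3x smaller cache at a
  forward-model perturbation well under the EM noise floor.
  `simulate_patch()` itself is exact (no pruning).
* CC is undefined on constant images; such cases return `NA` with a
  reason rather than a value, registration treats them as inadmissible
  poses, and the pipeline skips such patches.
* `max(e) = min(e)` in the EM makes the uniform density undefined; all
  posteriors become 1 and the state is flagged degenerate.
* The pipeline is deterministic: patches are processed in extraction
  order, and because each outer iteration registers all patches against
  the same frozen volume, the result is independent of that order.
* SSIM uses the standard form with `(μ_I² + μ_Ĩ² + c1)` in the
  denominator, a 7 × 7 uniform window, `k1 = 0.01`, `k2 = 0.03`, and
  the dynamic range of the reference image; the DSSIM map is
  `(1 − SSIM)/2`.

## Known limitations

* Rigid patches approximate affine or non-rigid deformation only to
  first order; very small patches weaken registration (less context),
  very large ones violate local rigidity — the multi-scale schedule is
  the compromise, and patch size remains the main tuning knob.
* Rapidly moving small structures that never appear consistently across
  stacks cannot reach consensus and reconstruct blurry; the rigidity
  map flags such regions rather than fixing them.
* The Gaussian slice profile is a surrogate for the true sequence
  profile; on real data the through-plane kernel is broader-tailed.
* Registration is intensity-based CC: stacks must be contrast-consistent
  (the intensity-matching step assumes gain-only differences).
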