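# pvr — patch-to-volume reconstruction for motion-corrupted multi-stack MRI

Fast 2D MRI sequences acquire sharp individual slices, but motion
between slice acquisitions (fetal movement, maternal breathing) corrupts
the assembled 3D stacks. Slice-to-volume registration (SVR) repairs this
by rigidly registering each whole slice to an iteratively super-resolved
volume — valid only where everything on a slice moves rigidly together,
i.e. a single masked organ. `pvr` implements **patch-to-volume
reconstruction (PVR)**, which relaxes the rigidity assumption to patch
scale so that large fields of view with independently moving parts
(whole uterus, fetal body plus placenta) can be reconstructed without a
region-of-interest mask. It is aimed at researchers in fetal/perinatal
MRI and anyone reconstructing isotropic volumes from thick-slice,
motion-corrupted multi-stack acquisitions.

## Method

Each low-resolution stack is modelled as `Y_i = D B T_i X + n_i`, where
`X` is the isotropic volume to recover, `T_i` rigid motion, `B` the
point-spread function (PSF), `D` slice sub-sampling. The loop:

1. choose the template stack (highest consecutive-slice correlation),
   match intensities (gain only), align all stacks rigidly in 3D;
2. decompose every slice into overlapping square patches (size `a`,
   stride `ω`) or SLIC superpixels (step `a`, dilated by `γ` pixels,
   optionally over a multi-scale schedule `a_i = a·1.5^i`);
3. register every patch rigidly to the current volume, maximizing
   cross-correlation;
4. classify residuals with an EM mixture — Gaussian inliers
   (variance `σ²`, proportion `c`) against uniform outliers — giving
   per-voxel weights `p` and per-patch posteriors `p̂ = √(Σp²/N)`;
   patches with `p̂ < 0.5` are excluded but may re-enter;
5. update the volume by preconditioned gradient descent on

   `Σ_s p̂_s Σ_j p_j (y_j − y*_j)² + λ Σ_i Σ_d φ((x_{i+d} − x_i)/(δ|d|)) / 26`

   where `y*` is the PSF-simulated patch, `φ(t) = 2√(1+t²) − 2`
   (edge-preserving), `δ ≈ 150` for data in [0, 1000], and
   `λ = 0.8 δ²` halves every outer iteration.

The PSF is a Gaussian-windowed truncated-Taylor sinc in-plane
(`sinc(x) = 1 − x²/3! + x⁴/5! − ...`, term count chosen from the
truncation bound `ε`) and a Gaussian slice profile through-plane. A
rigidity/uncertainty map — the PSF projection of `p·p̂` — flags regions
whose motion fit the rigid patch model. The package also ships a
procedural phantom plus synthetic-motion harness (rigid translation,
half-volume bulk rotation, combined skew with all six shear entries
`tan θ`) and CC / PSNR / SSIM / DSSIM metrics.

## Worked example

```r
library(pvr)

# phantom + three interleaved 1.25 x 1.25 x 2.5 mm stacks, corrupted by
# a combined skew of 1 degree
study <- simulate_study(size = 48, seed = 1,
                        motion = motion_spec("skew", theta_xyz = 1))

rec <- pvr_reconstruct(study$stacks,
                       pvr_config("square", patch_size = 32L, stride = 16L))
print(rec)
#> <pvr_recon> square variant: 38 x 38 x 37 @ 1.25 mm
#>   513 patches (0 excluded), 2 outer iterations

m <- reference_metrics(rec$volume, study$phantom)
cat(sprintf("PVR  : PSNR %.2f dB, SSIM %.3f, CC %.4f\n", m$psnr, m$ssim, m$cc))
#> PVR  : PSNR 26.02 dB, SSIM 0.933, CC 0.9829

for (i in seq_along(study$stacks)) {
  b <- reference_metrics(resample(study$stacks[[i]], rec$volume), study$phantom)
  cat(sprintf("stack %d upsampled: PSNR %.2f dB, SSIM %.3f, CC %.4f\n",
              i, b$psnr, b$ssim, b$cc))
}
#> stack 1 upsampled: PSNR 23.85 dB, SSIM 0.856, CC 0.9717
#> stack 2 upsampled: PSNR 22.56 dB, SSIM 0.852, CC 0.9621
#> stack 3 upsampled: PSNR 22.54 dB, SSIM 0.853, CC 0.9619
```

The reconstruction recovers about 2–3 dB PSNR over trilinear upsampling
of any corrupted input stack; `rec$rigidity` holds the rigidity map and
`rec$manifest` the per-iteration log, per-patch posterior table, and
overhead accounting.

Command-line wrappers live in `inst/cli/`:
`pvr-sim.R` (phantom + corrupted stacks with a JSON ground-truth
sidecar), `pvr-reconstruct.R` (NIfTI in, NIfTI + manifest out), and
`pvr-eval.R` (metric reports).

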