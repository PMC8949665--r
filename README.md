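# tvnls

Compressed-sensing image reconstruction and denoising with total-variation
(TV) and nonlocal self-similarity (NLS) regularization, solved by an
augmented-Lagrangian / alternating-direction scheme.

## The problem and the model

Images acquired through compressed sensing — or simply corrupted by noise —
must be recovered from

```
f = A u + ε
```

where `u ∈ R^N` is the unknown image, `A ∈ R^{M×N}` a linear measurement
operator (`A = I` for pure denoising) and `ε` additive noise. Least squares
alone is hopeless for `M < N` or strong noise, and classical TV
regularization alone over-smooths texture. The package therefore minimizes

```
min_u  1/2 ||A u − f||²  +  τ TV(u)  +  λ NLS(u)
```

* `TV(u) = ||D u||₁` — the anisotropic total variation (periodic forward
  differences `D = (D_h, D_v)`), which preserves edges and flattens smooth
  regions.
* `NLS(u) = Σ_i ||T₃D(Z_i)||₁` — for each reference block on a stride grid,
  the `m` most similar `n×n` blocks inside an `L×L` search window are
  stacked into a 3-D group `Z_i`; `T₃D` is a separable orthonormal 3-D
  DCT. The l1 norm of the group coefficients rewards images whose repeated
  structures (texture!) agree with each other.

The splitting `D u = w`, `u = x` turns this into a constrained problem whose
augmented Lagrangian is minimized by alternating three closed-form-ish
updates with multiplier ascent:

1. **w-update** — soft-thresholding in the gradient domain,
   `w = shrink(Du − γ/ρ_tv, τ/ρ_tv)`;
2. **u-update** — the exact normal equations
   `(AᵀA + ρ_tv DᵀD + ρ_nls I) u = Aᵀf + Dᵀ(ρ_tv w + γ) + ρ_nls x + φ`,
   solved in one 2-D FFT round trip when `A = I` (periodic `DᵀD` is
   diagonal in Fourier) and by conjugate gradients otherwise;
3. **x-update** — collaborative shrinkage: block-match, 3-D transform,
   soft-threshold every group coefficient, inverse transform, average
   overlapping blocks;

then `γ ← γ − ρ_tv(Du − w)`, `φ ← φ − ρ_nls(u − x)`.

The package also provides the classical wavelet-shrinkage baseline
(orthogonal Daubechies/Haar DWT, soft/hard rules, universal threshold
`σ√(2 ln N)`), Gaussian and salt-and-pepper noise simulators, a synthetic
phantom generator mixing piecewise-constant shapes with exactly periodic
texture, PSNR/SSIM metrics, an ablation harness and a command-line driver.

## Worked example

```r
library(tvnls)

ph    <- makePhantom(128, 128, texturePeriod = 8, nShapes = 6, seed = 0)
noisy <- addGaussianNoise(ph, sigma = 20, seed = 1)

res <- tvnlsDenoise(noisy, solverConfig(sigma = 20), groundTruth = ph)
wav <- waveletDenoise(noisy, waveletConfig(sigma = 20))

cat(sprintf("noisy:    PSNR %5.2f dB   SSIM %.3f\n",
            imagePSNR(ph, noisy), imageSSIM(ph, noisy)))
cat(sprintf("wavelet:  PSNR %5.2f dB   SSIM %.3f\n",
            imagePSNR(ph, wav), imageSSIM(ph, wav)))
cat(sprintf("tv+nls:   PSNR %5.2f dB   SSIM %.3f\n",
            imagePSNR(ph, res$image), imageSSIM(ph, res$image)))
```

prints

```
noisy:    PSNR 22.09 dB   SSIM 0.461
wavelet:  PSNR 23.80 dB   SSIM 0.455
tv+nls:   PSNR 30.36 dB   SSIM 0.838
```

The noisy observation sits at 22 dB; universal-threshold wavelet shrinkage
recovers under 2 dB because the global threshold trades texture for flat
regions; the TV+NLS reconstruction gains over 8 dB and nearly doubles the
structural-similarity score because the periodic texture is matched against
its own repetitions instead of being smoothed away.
`res$state@history` holds the per-iteration constraint residuals and PSNR;
`runAblation()` quantifies each regularizer's contribution separately.

A command-line interface with the same functionality (subcommands
`phantom`, `simulate-noise`, `denoise`, `cs-recover`, `evaluate`,
`experiment`) is installed at
`system.file("cli", "tvnls.R", package = "tvnls")`.

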