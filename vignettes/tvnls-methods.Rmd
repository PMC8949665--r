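---
title: "Reconstruction with total variation and nonlocal self-similarity: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction with total variation and nonlocal self-similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvnls)
```

## The model

The package recovers an image $u \in \mathbb{R}^N$ from linear measurements
$f = A u + \varepsilon$ by solving

$$\min_u \; \tfrac12 \lVert A u - f\rVert_2^2 \;+\; \tau\,\mathrm{TV}(u)
\;+\; \lambda\,\mathrm{NLS}(u),$$

with the anisotropic total variation
$\mathrm{TV}(u) = \lVert D u \rVert_1$ (periodic forward differences) and
the nonlocal self-similarity penalty
$\mathrm{NLS}(u) = \sum_i \lVert T_{3D}(Z_i) \rVert_1$, where $Z_i$ stacks
the $m$ blocks most similar to the $i$-th reference block and $T_{3D}$ is a
separable orthonormal 3-D DCT-II. TV assumes the image is approximately
piecewise constant; NLS assumes repeated local structure (texture,
regular patterns). The two priors are complementary: TV flattens smooth
regions and keeps edges sharp, NLS protects exactly the oscillatory content
TV would erase.

The constrained splitting $Du = w$, $u = x$ yields the augmented Lagrangian

$$L_A = \tfrac12\lVert Au-f\rVert^2 + \tau\lVert w\rVert_1
 + \lambda\lVert\theta_x\rVert_1 - \gamma^\top(Du-w) - \varphi^\top(u-x)
 + \tfrac{\rho_{tv}}2\lVert Du-w\rVert^2 + \tfrac{\rho_{nls}}2\lVert u-x\rVert^2,$$

minimized by alternating the three updates (gradient-domain shrinkage,
a linear solve, collaborative shrinkage) followed by the dual ascent
$\gamma \leftarrow \gamma - \rho_{tv}(Du-w)$,
$\varphi \leftarrow \varphi - \rho_{nls}(u-x)$. The u-subproblem is solved
through its exact normal equations,

$$(A^\top A + \rho_{tv} D^\top D + \rho_{nls} I)\,u
 = A^\top f + D^\top(\rho_{tv} w + \gamma) + \rho_{nls}x + \varphi .$$

With periodic differences $D^\top D$ is the 5-point Laplacian, diagonal in
the 2-D Fourier basis, so for $A = I$ the solve is one FFT round trip and
exact to machine precision; for general operators a conjugate-gradient path
with matched `applyOperator`/`adjointOperator` contracts is used. The test
suite verifies both paths against dense linear algebra on 8×8 instances.

Initialization follows the constrained-splitting convention: $u_0 = f$ for
$A = I$ (or $A^\top f$ otherwise, since a length-$M$ measurement vector
cannot initialize a length-$N$ image), with $w_0 = x_0 = 0$ and zero
multipliers.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau` | `0.1 * sigma` | intensity | TV weight |
| `lambdaNLS` | see below | — | NLS weight |
| `rhoTV`, `rhoNLS` | 1 | — | penalty parameters (dual step sizes) |
| `sigma` | MAD estimate | intensity | noise level driving both weights |
| `blockSize` $n$ | 8 | px | patch side |
| `groupSize` $m$ | 16 | — | blocks per group |
| `searchWindow` $L$ | 39 | px | matching window side |
| `step` | 4 | px | reference-block stride (overlapping) |
| `thresholdScale` $c$ | 2 | — | factor in the coefficient threshold |
| `maxOuter` / `maxInner` | 50 / 1 | — | iteration caps |
| `tolRelChange` / `tolResidual` | 1e-4 / 1e-3 | — | stopping rule |

The x-update shrinks every group coefficient at
$\mathrm{thr} = c\,K\lambda/(N\rho_{nls})$ with $K = n^2 m$ the per-group
coefficient count and $N$ the image pixel count (the whole-image reading of
the energy-equivalence argument; the per-group alternative only rescales
$\lambda$). Because that mapping makes the *effective* threshold — not
$\lambda$ itself — the quantity with physical meaning, the default
`lambdaNLS` is resolved so that $\mathrm{thr} = 1.1\,\hat\sigma$. A
threshold proportional to the noise level is the standard operating point
of collaborative shrinkage; the constants $0.1$ (for $\tau$) and $1.1$ were
fixed once on the $\sigma = 20$ phantom conditions and are deliberately not
image-adaptive. Setting a weight to zero removes the corresponding
constraint entirely, which makes the unregularized case ($u = f$) exact in
one iteration rather than a slowly-converging limit.

When `sigma` is not supplied it is estimated by the wavelet MAD rule
(median absolute finest-level diagonal coefficient / 0.6745). For
salt-and-pepper noise this "pseudo-σ" is large (impulses are broadband),
which conveniently strengthens both priors; the data fidelity remains the
Gaussian quadratic — no l1-fidelity variant is provided.

**Block matching** uses squared Euclidean distance on raw intensities,
candidates enumerated fully inside both the image and the window centred on
the reference block, ties broken by row-major scan order, the reference
always member 1. By default (`matchOn = "initial"`) matching is performed
on the initial estimate and the group structure is held fixed across
iterations: with fixed groups the x-step is a stationary operator, the
constraint residuals contract by orders of magnitude, and the whole
iteration behaves like a convergent splitting scheme. Re-matching on the
current iterate (`matchOn = "iterate"`) is available and is useful for
compressed-sensing recovery, where the initial back-projection is too
aliased to match on, but it leaves the residuals plateauing at the level of
the matching churn.

**Stopping.** The loop ends when the relative change of $u$ falls below
`tolRelChange` *and* both constraint residuals fall below
`tolResidual`·$\sqrt N$, or at `maxOuter`. The inner/outer structure allows
several alternating sweeps per multiplier update (`maxInner`), but one
sweep is the default and is what the convergence checks pin.

## The synthetic phantom

`makePhantom()` generates the test conditions: a mid-gray background,
overlapping constant-intensity rectangles and disks (exercising TV), and a
bottom strip tiled with an *exactly* periodic texture (exercising NLS: any
block inside the strip has dozens of exact duplicates within the default
search window). The texture tile is a cyclically smoothed random field
rescaled to ±35 around the background level: smoothing gives the texture
the decaying spectrum of natural periodic patterns — a raw white-noise tile
would be unlike any real texture and would make every smoothing prior
strictly harmful on half the image. All randomness is seeded; identical
seeds give identical images.

What the phantom does *not* emulate: photographic edge blur, spatially
varying illumination, texture that is only approximately self-similar, and
correlated sensor noise. Passing the end-to-end checks therefore
demonstrates that the solver exploits exact self-similarity and piecewise
constancy under white noise, not that it matches published numbers on
standard photographs — those depend on unpublished parameter settings and
external test images and are deliberately out of scope.

## Numerical choices

* **Periodic boundaries** for the gradient (enables the spectral u-solve)
  and for the wavelet filter bank. A periodized orthogonal bank stays
  exactly orthogonal at every dyadic level, which makes energy conservation
  and the "shrinkage never increases energy" property exact rather than
  approximate; this is why periodization was chosen over symmetric
  extension for the baseline.
* **Orthonormal transforms everywhere** (DCT-II within blocks and along the
  similarity axis, optionally a full-depth Haar along the axis; db4/Haar
  for the baseline DWT). Orthonormality is required for the
  coefficient-domain threshold mapping to be exact per group.
* **Aggregation** divides by the per-pixel coverage count (uniform
  weights); the stride grid always appends the last in-range position, so
  every pixel is covered and the pass-through branch is only a safeguard.
* **Shrinkage convention**: $\mathrm{sgn}(v)\max(|v|-t, 0)$ componentwise —
  the l1 proximal map — in the gradient domain, the group-coefficient
  domain and the wavelet domain alike.
* **Degenerate inputs**: constant images have zero TV, zero MAD estimate
  and a single DC group coefficient; zero thresholds reproduce the input to
  numerical precision; identical images give SSIM exactly 1 and a flagged
  infinite PSNR.
* **SSIM** uses $K_1 = 0.01$, $K_2 = 0.03$, $c_3 = c_2/2$, and by default a
  sliding 8×8 uniform window over fully interior positions with unbiased
  sample moments; the whole-image "global" mode is retained. With
  $c_3 = c_2/2$ anti-correlated images can score negative; an optional
  clamp to $[0,1]$ exists and is off by default, and the CLI records which
  mode produced its numbers.
* **Colour images** are processed channel by channel with shared
  parameters; metrics average over channels.

## Problem sizes in the checks

The unit and property tests run on 2×2 up to 64×64 instances against
brute-force, dense-matrix and grid/probe oracles. The end-to-end checks use
the 128×128 phantom with $\sigma = 20$ Gaussian noise (seeds 0–9), the 20 %
salt-and-pepper condition, a 5-seed regularizer ablation, and 32×32
compressed-sensing recovery at 85 % sampling — sizes chosen so the full
suite completes in a few minutes on one core while keeping every matched
group, residual trajectory and PSNR comparison statistically meaningful.

## Known limitations

* The descent property of the alternating sweep is exact only when the
  group partition makes the x-step an exact proximal map; with overlapping
  groups the x-step is the standard collaborative approximation, and the
  augmented Lagrangian can fluctuate at the aggregation level (the test
  suite checks descent in the exact configuration).
* Block matching costs $O(N L^2 n^2 / \text{step}^2)$ per pass and
  dominates the run time; it is compiled code, but very large images or
  windows will be slow on one core.
* The universal wavelet threshold is known to over-smooth; it is included
  as the classical reference point, not as a competitive denoiser.
* No Wiener second stage, no learned dictionaries, no RIP verification
  (combinatorial), and no l1 data fidelity for impulse noise.
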