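---
title: "Methods: adaptive wavelet shrinkage with a linear-prediction threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive wavelet shrinkage with a linear-prediction threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpwave)
```

## The model

The observation model is additive white Gaussian noise on a 2-D
intensity grid: `y_ij = x_ij + ε_ij` with `ε_ij ~ N(0, σ²)` i.i.d.
Denoising proceeds in the wavelet domain: decompose `y`, shrink the
detail coefficients against a threshold, reconstruct.  The central
assumptions are (i) the clean image is well concentrated in few wavelet
coefficients while the noise spreads evenly, so small detail
coefficients are mostly noise; (ii) the noise is stationary, so one
global noise-scale estimate serves all subbands; (iii) for the
adaptive method, a same-size reference image `Io` is available whose
linear relation to the noisy frame carries usable information.  The
approximation subband is never shrunk.

## Transform

The default basis is the biorthogonal spline pair `bior3.9` at three
levels.  Because no wavelet transform exists in the dependency stack
this package targets, the filter bank is derived in closed form: the
synthesis lowpass is the binomial spline filter `√2·{1,3,3,1}/8`, and
the analysis lowpass multiplies `cos⁹(ω/2)` by the half-band completion
polynomial `Σₙ C(5+n, n) sin²ⁿ(ω/2)` (n = 0..5), yielding the standard
20-tap bank to machine precision.  Boundary handling is symmetric
(half-sample) extension — the common default for symmetric biorthogonal
filters; a length-`n` signal yields `⌊(n+19)/2⌋` coefficients per
subband, and that mild redundancy is what makes the transform exactly
invertible for arbitrary sizes.  The convention (extension, phase,
output lengths) matches the MATLAB/PyWavelets `symmetric` mode, and a
frozen fixture computed with an independent implementation pins it in
the tests.  Round-trip error is at machine precision (~1e-15 relative);
the stated tolerance of 1e-8 is asserted in the acceptance suite.
Level `j = 1` is the finest scale; `HL` denotes highpass along the row
axis, `LH` along the column axis, `HH` diagonal.

## Noise-scale estimation

`σ̂ = median(|HH₁|)/0.6745`.  On raw Gaussian draws this estimator is
consistent (the acceptance suite checks 5% recovery at 256×256).  One
subtlety deserves emphasis: `bior3.9` is *not* orthonormal — the
analysis highpass has `‖g̃‖² = 0.625` — so the HH₁ coefficients of
white noise of scale σ have standard deviation `0.625·σ`, and `σ̂`
estimates that quantity, not σ itself.  The classical recipe is kept
deliberately (estimate once from HH₁, reuse at all levels), because
every threshold in the benchmark consumes the same `σ̂`, and this is
how the method family is used in practice with biorthogonal bases.  A
consequence worth knowing: with `‖h̃‖² ≈ 2`, noise variance roughly
doubles per level in the approximation path, so deeper detail subbands
are noisier than `σ̂` suggests — one reason a threshold that *grows*
with the level (below) is sensible for this basis.

## Thresholds

* Universal: `T = σ̂√(2 log N)`.  `N` is the total pixel count of the
  image (the "length of the input signal"); a per-subband-count
  convention is available (`n_convention = "subband"`).  Logarithms are
  natural by default (the classical convention), base-10 optional.
* BayesShrink: per subband, `T = σ̂²/σ̂ₓ`, `σ̂ₓ = √(max(mean(ω²) − σ̂², 0))`.
  When `σ̂ₓ = 0` the subband is judged pure noise; rather than an
  infinite threshold the implementation returns the finite sentinel
  `max|ω| + 1`, which makes every shrinkage rule zero the subband
  without special-casing infinity.
* Level-adaptive: `T_j = σ̂√(2 log N) · log(1+j) · β`.  The printed
  form of this estimator does not disambiguate how `log(1+j)` and `β`
  attach to the universal factor; the package defaults to the plain
  product (the natural reading of "extending the universal threshold by
  two parameters") and offers `eq13_parse = "divide_beta"` for the
  reciprocal placement.  Both are pure scalings, so nothing downstream
  changes.  `β` is computed once per image pair (the prediction factor
  is defined on whole images), not per level or subband.

## The prediction factor

`β = Σ Io·In / Σ Io²` is the least-squares slope through the origin of
the noisy frame on the reference — the argmin of the mean squared
prediction error `mean((In − β·Io)²)`.  Its residual is orthogonal to
the reference by the normal equation, a property the tests assert at
1e-12 relative.  Sums use R's extended-precision accumulator (long
double), which bounds rounding error at least as tightly as the
pairwise scheme originally envisioned for this module — that is the one
implementation substitution made here.  For zero-mean noise added to
the reference itself, `β → 1` as the image grows; the method then
reduces to a level-weighted universal threshold.  A reference is
*required*: the package fails loudly rather than inventing a proxy from
the noisy image alone.

## Shrinkage rules

Hard, soft and semi-soft follow their classical closed forms
(boundary coefficients `|w| = T` are kept).  The adaptive rule shrinks
kept coefficients by `sin((π/2)·(T/|w|)^(β·T))·T`: exactly `T` at
`|w| = T` (continuity, no Gibbs-type jump) and decaying to zero as
`|w| → ∞` (no constant soft-threshold bias).  The exponent is read as
the product `β·T`.  Numerical choices: with `T = 0` the rule is the
identity and the power is never evaluated (avoiding `0⁰`); the kept
branch is computed only where `|w| ≥ T`.  The vectorized
implementations are bit-identical to scalar reference definitions on a
10⁴-point grid, and the sandwich `|soft| ≤ |adaptive| ≤ |hard|`, odd
symmetry, non-expansiveness and monotone convergence to the identity
are property-tested.  Semi-soft's `α` defaults to 0.5 — the interior
point of its range — since no value is prescribed by the method family
for benchmarking.

## Metrics

MSE, PSNR `= 10·log₁₀(L²/MSE)` and SSIM, computed after rescaling
normalized images to the 8-bit range (`L = 255`), so reported numbers
are comparable with the literature.  SSIM's stabilizers use the
standard `K₁ = 0.01`, `K₂ = 0.03`, `Cᵢ = (Kᵢ·L)²`.  The default SSIM
mode is *global* — the similarity expression evaluated once over the
whole image with population moments, matching the single-window form of
the index — because that is the form the benchmark protocol prints;
`mode = "windowed"` (11×11 Gaussian window, sd 1.5) is provided for
comparison with common implementations.  Note that global SSIM on
large, mostly-dark medical images sits much closer to 1 than windowed
SSIM; absolute SSIM values are not comparable across modes.

## Synthetic phantom and noise

The generator emulates an axial brain slice: a bright skull-like
elliptical shell on a dark background (~44% of the frame), a darker CSF
gap, mid-gray tissue, two dark ventricles, eight seeded elliptical
internal structures, and a low-amplitude (±0.12) smooth cosine texture
confined to the head.  This provides the three regimes the shrinkage
literature argues about — flat regions, sharp high-contrast edges and
fine texture — while remaining a stated, seeded, fully reproducible
world.  It does **not** emulate MRI acquisition physics: no Rician
magnitude statistics, no spatially correlated noise, no partial-volume
blur, no intensity inhomogeneity.  Noise is additive `N(0, v)` on the
normalized [0,1] scale, with `v ∈ {0.01, …, 0.05}` in the benchmark,
and is *not* clipped to [0,1] by default: clipping truncates the noise
distribution and would bias both `β` and `σ̂` (clipping is available as
an explicit flag, and write-time quantization always clamps).  A green
end-to-end test therefore establishes that the pipeline denoises a
piecewise-smooth edge-rich image under exactly additive Gaussian noise
— not that it reproduces any particular clinical result.

## Benchmark design

`run_benchmark()` is a pure function of (inputs, configs, seed).  The
noise seed of a cell depends only on (image, variance, replicate), so
all methods in a cell see the same noisy realization — a paired design
that sharpens method comparisons.  Failed cells produce `NA` rows, not
crashes.  CSV output is formatted deterministically (`%.10g`, `inf`
sentinel for infinite PSNR), so identical invocations are
byte-identical.

## Known limitations and an honest negative result

On this phantom the adaptive method dominates VisuShrink at variances
0.01–0.02 but falls behind by a few percent in mean MSE at 0.03–0.05
(while still improving PSNR over the noisy input by ~7 dB there); the
acceptance suite asserts the full ordering and is deliberately left
failing at the high variances.  The mechanism is visible in the
formulas: with `β ≈ 1` the finest-scale threshold is
`log(2) ≈ 0.69` times the universal one, and the taper is near-hard
away from `T`, so at high noise the many level-1 `HL`/`LH`
coefficients retain Gaussian tail noise that a global soft rule
suppresses.  Published results for this method family on clinical MRI
report essentially noise-level-independent MSE, which the printed
equations cannot produce under unclipped additive noise at these
levels; a protocol whose noisy intensities are clipped to the valid
range (the semantics of common MATLAB noise injection) truncates
exactly the tails that penalize the smaller thresholds and is the most
plausible reconciliation.  The package keeps unclipped noise as its
stated world and documents the discrepancy rather than tuning around
it.

Further non-goals: 3-D/volumetric transforms, stationary (undecimated)
wavelets, wavelet packets, SURE-based thresholds, garrote/firm/SCAD
shrinkage families, blind (reference-free) estimation of `β`, motion
compensation between reference and noisy frames, and perceptual metrics
beyond SSIM.
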