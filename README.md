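# lpwave

Wavelet-shrinkage noise reduction for 2-D grayscale images — in
particular brain MR slices corrupted by additive white Gaussian noise —
built around a reference-weighted adaptive threshold and a continuous
sine-tapered shrinkage rule, with the classical VisuShrink and
BayesShrink estimators, full-reference quality metrics and a seeded
synthetic-phantom benchmark harness.

## The method

A noisy image `y = x + ε`, `ε ~ N(0, σ²)` i.i.d. per pixel, is taken to
the wavelet domain (`ω = W y`, biorthogonal `bior3.9` basis, 3 levels,
symmetric boundary extension), its detail coefficients are shrunk
against a threshold `T`, and the estimate is `x̂ = W⁻¹ ω̂`.  The noise
scale is estimated robustly from the finest diagonal subband,
`σ̂ = median(|HH₁|) / 0.6745`.

Supported thresholds:

* **universal (VisuShrink)** — `T = σ̂ √(2 log N)`, global;
* **BayesShrink** — `T = σ̂² / σ̂ₓ` per subband, with
  `σ̂ₓ = √(max(mean(ω²) − σ̂², 0))`;
* **level-adaptive (the package's focus)** —
  `T_j = σ̂ √(2 log N) · log(1 + j) · β`, where `j` is the
  decomposition level and `β = Σ Io·In / Σ Io²` is the linear
  prediction factor: the least-squares slope through the origin
  relating a clean (or earlier-frame) reference `Io` to the noisy
  image `In`.

Shrinkage rules: hard, soft, semi-soft (`α ∈ [0,1]`), and the adaptive
sine-tapered rule

```
ω̂ = sign(ω) · (|ω| − sin((π/2) · (T/|ω|)^(β·T)) · T)   for |ω| ≥ T,   0 otherwise
```

which is continuous at `T` (like soft) yet converges to the identity
for large coefficients (like hard), avoiding both the pseudo-Gibbs
oscillations of hard thresholding and the constant bias of soft
thresholding.  Quality is reported as MSE, PSNR `= 10 log₁₀(L²/MSE)`
and SSIM on the 8-bit (`L = 255`) scale.

No wavelet package exists in the target R stack, so the `bior3.9`
filter bank is derived in closed form (CDF biorthogonal-spline
construction) and the symmetric-mode 2-D DWT is implemented here; both
are verified against an independent reference implementation in the
test suite.

## Worked example

```r
library(lpwave)

clean <- brain_phantom(256, seed = 1)                 # synthetic brain slice in [0,1]
noisy <- add_gaussian_noise(clean, 0.01, seed = 7)    # variance 0.01, unclipped
cfg   <- denoise_config(threshold_method = "proposed", shrink_method = "adaptive")
out   <- denoise(noisy, cfg, reference = clean)

attr(out, "denoise_info")[c("sigma", "beta")]
#> $sigma [1] 0.06327448      # median(|HH1|)/0.6745 (absorbs the bior filter gain)
#> $beta  [1] 0.9998058       # ~1: the noisy image is an unbiased copy of the reference

metrics_report(clean, noisy)
#> <metrics_report> MSE = 650.8  PSNR = 20.00 dB  SSIM = 0.9552 (global, L = 255)
metrics_report(clean, out)
#> <metrics_report> MSE = 225.8  PSNR = 24.59 dB  SSIM = 0.9834 (global, L = 255)
```

The denoiser removed two thirds of the mean squared error (651 → 226 on
the 0–255 scale, a 4.6 dB PSNR gain) and raised structural similarity
from 0.955 to 0.983.  The benchmark harness compares methods on shared
noise realizations:

```r
recs <- run_benchmark(list(phantom = clean), c(0.01, 0.05),
                      benchmark_methods(), reps = 3, seed = 42)
print(recs)
#> == phantom ==
#> MSE
#>   variance          0.01      0.05
#>   bayesshrink      390.6      1776
#>   proposed         227.1     591.5
#>   visushrink       250.5     540.2
#> ...
write_records_csv(recs, "results.csv")
```

At low noise the adaptive method dominates; at the highest variances
its smaller fine-scale threshold retains more noise than VisuShrink's
aggressive soft rule on this phantom (see the methods vignette for the
analysis).

## Command line

```sh
Rscript inst/cli/lpwave phantom   --size 256 --seed 1 --out phantom.png
Rscript inst/cli/lpwave denoise   --input noisy.png --output out.png \
        --reference clean.png --threshold proposed --shrink adaptive
Rscript inst/cli/lpwave metrics   --reference clean.png --test out.png
Rscript inst/cli/lpwave benchmark --phantom-size 256 --reps 10 --seed 42 --out results.csv
```

Exit codes: 0 success, 2 configuration error, 3 I/O error, 4 numerical
failure.  (After installation the launcher lives at
`system.file("cli", "lpwave", package = "lpwave")`.)

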