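Package: lpwave
Title: Adaptive Wavelet Shrinkage Denoising for Brain MRI with a
    Linear-Prediction Threshold
Version: 0.1.0
Authors@R:
    person("lpwave", "developers", email = "lpwave@example.org",
           role = c("aut", "cre"))
Description: Wavelet-domain noise reduction for two-dimensional grayscale
    images, aimed at additive Gaussian noise in brain magnetic resonance
    images.  Implements a multilevel biorthogonal ('bior3.9') discrete
    wavelet transform with symmetric boundary handling, the classical
    VisuShrink (universal) and BayesShrink threshold estimators, a
    reference-weighted adaptive threshold scaled by the decomposition
    level and a linear prediction factor, hard/soft/semi-soft shrinkage
    and a continuous sine-tapered shrinkage rule, full-reference image
    quality metrics (MSE, PSNR, SSIM), a seeded synthetic brain-phantom
    and noise generator, and a reproducible benchmark harness with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
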