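#' Synthetic brain-like phantom
#'
#' Generates a piecewise-smooth grayscale phantom loosely modelled on an
#' axial brain MR slice: a bright skull-like ring, a darker
#' cerebrospinal gap, mid-gray brain tissue, a pair of dark ventricles,
#' a seeded collection of nested elliptical structures, and a
#' low-amplitude smooth texture.  The composition provides both the
#' smooth regions and the sharp edges that wavelet shrinkage methods are
#' judged on, without requiring any external MRI data.  Output is
#' normalized to `[0, 1]` and is bit-identical for a fixed seed.
#'
#' @param size Side of the square image (>= 32, default 256).
#' @param n_structures Number of random internal ellipses (default 8).
#' @param contrast_range Intensity range the random structures draw
#'   from, inside `[0, 1]` (default `c(0.15, 0.95)`).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return An `image_grid` with `dynamic_range = 1`.
#' @examples
#' ph <- brain_phantom(64, seed = 1)
#' range(as.matrix(ph))
#' @export
brain_phantom <- function(size = 256L, n_structures = 8L,
                          contrast_range = c(0.15, 0.95), seed = 1L) {
  size <- as.integer(size)
  if (is.na(size) || size < 32L) {
    stop("`size` must be an integer >= 32", call. = FALSE)
  }
  if (length(contrast_range) != 2L || any(contrast_range < 0) ||
      any(contrast_range > 1) || contrast_range[1] > contrast_range[2]) {
    stop("`contrast_range` must be an increasing pair inside [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    u <- matrix(rep(seq(-1, 1, length.out = size), size), size, size)
    v <- t(u)
    inside <- function(cx, cy, a, b, ang) {
      ca <- cos(ang); sa <- sin(ang)
      xr <- (u - cx) * ca + (v - cy) * sa
      yr <- -(u - cx) * sa + (v - cy) * ca
      (xr / a)^2 + (yr / b)^2 <= 1
    }
    img <- matrix(0, size, size)
    img[inside(0, 0, 0.92, 0.78, 0)] <- 0.95        # skull shell
    img[inside(0, 0, 0.84, 0.70, 0)] <- 0.10        # CSF gap
    img[inside(0, 0, 0.80, 0.66, 0)] <- 0.45        # brain tissue
    brain <- inside(0, 0, 0.80, 0.66, 0)
    # ventricles: two dark curved ellipses near the center
    for (s in c(-1, 1)) {
      vent <- inside(s * 0.14, -0.05, 0.10, 0.26, s * 0.35)
      img[vent & brain] <- 0.12
    }
    # seeded nested structures (gray-matter folds, lesions, nuclei)
    for (k in seq_len(n_structures)) {
      cx <- stats::runif(1, -0.45, 0.45)
      cy <- stats::runif(1, -0.40, 0.40)
      a  <- stats::runif(1, 0.04, 0.22)
      b  <- stats::runif(1, 0.04, 0.22)
      ang <- stats::runif(1, 0, pi)
      val <- stats::runif(1, contrast_range[1], contrast_range[2])
      sel <- inside(cx, cy, a, b, ang) & brain
      img[sel] <- val
    }
    # smooth low-amplitude texture inside the head
    tex <- matrix(0, size, size)
    for (k in 1:4) {
      fx <- stats::runif(1, 1, 4); fy <- stats::runif(1, 1, 4)
      phx <- stats::runif(1, 0, 2 * pi); phy <- stats::runif(1, 0, 2 * pi)
      tex <- tex + cos(pi * fx * u + phx) * cos(pi * fy * v + phy)
    }
    img <- img + 0.03 * tex * brain
    img <- pmin(pmax(img, 0), 1)
    image_grid(img, dynamic_range = 1)
  })
}

#' Add white Gaussian noise to an image
#'
#' Adds i.i.d. zero-mean Gaussian noise of the given variance to every
#' pixel, emulating the standard corruption protocol for denoising
#' benchmarks (variances quoted on the normalized `[0, 1]` intensity
#' scale).  The output is deliberately **not** clipped to the valid
#' range by default: clipping truncates the noise distribution and
#' biases both the prediction factor and the wavelet-domain noise
#' estimate.  Pass `clip = TRUE` for display purposes.
#'
#' @param image Clean image (`image_grid` or matrix), expected on a
#'   normalized scale.
#' @param variance Noise variance (> 0).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param clip Clamp the result into `[0, dynamic range]`?
#' @return An `image_grid` with the same dynamic range as the input.
#' @export
add_gaussian_noise <- function(image, variance, seed = NULL, clip = FALSE) {
  img <- as_image_grid(image)
  if (!is.numeric(variance) || length(variance) != 1L ||
      !is.finite(variance) || variance <= 0) {
    stop("`variance` must be a single number > 0", call. = FALSE)
  }
  noisy <- with_seed(seed, {
    img$pixels + stats::rnorm(length(img$pixels), 0, sqrt(variance))
  })
  if (clip) noisy <- pmin(pmax(noisy, 0), img$L)
  image_grid(noisy, img$L)
}
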