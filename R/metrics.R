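#' @title Full-reference image quality metrics
#' @description
#' Mean squared error, peak signal-to-noise ratio and structural
#' similarity between a reference image and a reconstruction, in the
#' images' native intensity scale.  `psnr()` needs the dynamic range
#' `L` of that scale (255 for 8-bit data); identical images give
#' `MSE = 0`, `PSNR = Inf`, `SSIM = 1`.
#' @name quality-metrics
NULL

match_pixels <- function(x, y) {
  mx <- pixels_of(x); my <- pixels_of(y)
  if (!identical(dim(mx), dim(my))) {
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(mx), ncol(mx), nrow(my), ncol(my)), call. = FALSE)
  }
  list(x = mx, y = my)
}

#' @describeIn quality-metrics Mean of squared differences,
#'   `mean((x - y)^2)`.
#' @param x,y Images (`image_grid` or matrix) of identical dimensions.
#' @export
mse <- function(x, y) {
  p <- match_pixels(x, y)
  mean((p$x - p$y)^2)
}

#' @describeIn quality-metrics `10 * log10(L^2 / MSE)` in dB; `Inf`
#'   when the images are identical.
#' @param L Dynamic range of the intensity scale (> 0).
#' @export
psnr <- function(x, y, L = 255) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("`L` must be a single positive number", call. = FALSE)
  }
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(L^2 / m)
}

# SSIM of one (possibly weighted) window; population moments
ssim_window <- function(mx, my, sxx, syy, sxy, C1, C2) {
  ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
}

# separable Gaussian-weighted moving sums with symmetric padding
gauss_filter2 <- function(m, kernel) {
  k <- length(kernel)
  r <- (k - 1L) %/% 2L
  fold <- function(mat) {
    n <- nrow(mat)
    ext <- mat[sym_ext_index(n, r), , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (j in seq_len(k)) {
      out <- out + kernel[j] * ext[seq_len(n) + (j - 1L), , drop = FALSE]
    }
    out
  }
  t(fold(t(fold(m))))
}

#' @describeIn quality-metrics Structural similarity.  `mode =
#'   "global"` (default) evaluates the SSIM expression once over the
#'   whole image with population moments, matching the single-window
#'   formula; `mode = "windowed"` averages it over 11x11
#'   Gaussian-weighted (sd 1.5) sliding windows, the convention of
#'   common SSIM implementations.  Stabilizers are `C1 = (K1*L)^2`,
#'   `C2 = (K2*L)^2`.
#' @param mode `"global"` or `"windowed"`.
#' @param K1,K2 Stabilizer constants (defaults 0.01 and 0.03).
#' @export
ssim <- function(x, y, L = 255, mode = c("global", "windowed"),
                 K1 = 0.01, K2 = 0.03) {
  mode <- match.arg(mode)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    stop("`L` must be a single positive number", call. = FALSE)
  }
  p <- match_pixels(x, y)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  if (mode == "global") {
    n <- length(p$x)
    mx <- mean(p$x); my <- mean(p$y)
    sxx <- mean(p$x^2) - mx^2
    syy <- mean(p$y^2) - my^2
    sxy <- mean(p$x * p$y) - mx * my
    return(ssim_window(mx, my, sxx, syy, sxy, C1, C2))
  }
  # 11x11 Gaussian window, sd 1.5, normalized to sum 1
  t0 <- seq(-5, 5)
  kernel <- exp(-t0^2 / (2 * 1.5^2))
  kernel <- kernel / sum(kernel)
  mx <- gauss_filter2(p$x, kernel)
  my <- gauss_filter2(p$y, kernel)
  sxx <- gauss_filter2(p$x^2, kernel) - mx^2
  syy <- gauss_filter2(p$y^2, kernel) - my^2
  sxy <- gauss_filter2(p$x * p$y, kernel) - mx * my
  mean(ssim_window(mx, my, sxx, syy, sxy, C1, C2))
}

#' Bundle the three metrics for one image pair
#'
#' Images carried on a normalized scale are rescaled to `L` before the
#' metrics are evaluated, so reported MSE/PSNR are on the conventional
#' 8-bit scale regardless of the internal representation.
#'
#' @param reference,test Images of identical dimensions.  If they are
#'   `image_grid`s their pixel values are divided by their own dynamic
#'   range and multiplied by `L` first.
#' @param L Dynamic range of the reporting scale (default 255).
#' @param ssim_mode `"global"` or `"windowed"`.
#' @return A `metrics_report`: list with `mse`, `psnr_db`, `ssim`, `L`,
#'   `ssim_mode`.
#' @export
metrics_report <- function(reference, test, L = 255,
                           ssim_mode = c("global", "windowed")) {
  ssim_mode <- match.arg(ssim_mode)
  rescale <- function(img) {
    if (inherits(img, "image_grid")) img$pixels / img$L * L else pixels_of(img)
  }
  rx <- rescale(reference); tx <- rescale(test)
  structure(
    list(
      mse = mse(rx, tx),
      psnr_db = psnr(rx, tx, L),
      ssim = ssim(rx, tx, L, mode = ssim_mode),
      L = L,
      ssim_mode = ssim_mode
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> MSE = %.4g  PSNR = %s dB  SSIM = %.4f (%s, L = %g)\n",
              x$mse, if (is.infinite(x$psnr_db)) "inf" else sprintf("%.2f", x$psnr_db),
              x$ssim, x$ssim_mode, x$L))
  invisible(x)
}
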