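#' Linear prediction factor between a reference and a noisy image
#'
#' The least-squares slope through the origin relating a clean reference
#' image `Io` to a noisy observation `In`:
#'
#' `beta = sum(Io * In) / sum(Io^2)`
#'
#' i.e. the scalar minimizing the mean squared prediction error
#' `mean((In - beta * Io)^2)`.  When the noisy image is the reference
#' plus zero-mean noise, `beta` concentrates near 1; an intensity
#' rescaling of the noisy image scales `beta` accordingly.  Sums are
#' accumulated in extended precision (R's long-double accumulator), so
#' rounding error is negligible at image sizes.
#'
#' @param reference Clean reference image (`image_grid` or matrix),
#'   not identically zero.
#' @param noisy Noisy image of identical dimensions.
#' @param reference_id Optional identifier recorded for provenance.
#' @return A `prediction_factor`: list with `beta`, `numerator`,
#'   `denominator`, `reference_id`.
#' @examples
#' io <- matrix(1:4, 2)
#' linear_prediction_factor(io, 2 * io)$beta  # exactly 2
#' @export
linear_prediction_factor <- function(reference, noisy, reference_id = "reference") {
  io <- pixels_of(reference)
  im <- pixels_of(noisy)
  if (!identical(dim(io), dim(im))) {
    stop(sprintf("shape mismatch: reference is %dx%d, noisy is %dx%d",
                 nrow(io), ncol(io), nrow(im), ncol(im)), call. = FALSE)
  }
  den <- sum(io^2)
  if (den == 0) {
    stop("reference image is identically zero; the prediction factor is undefined (supply a non-degenerate reference)",
         call. = FALSE)
  }
  num <- sum(io * im)
  structure(
    list(beta = num / den, numerator = num, denominator = den,
         reference_id = reference_id),
    class = "prediction_factor"
  )
}

#' @export
print.prediction_factor <- function(x, ...) {
  cat(sprintf("<prediction_factor> beta = %g (reference: %s)\n",
              x$beta, x$reference_id))
  invisible(x)
}

#' Prediction residual image
#'
#' Elementwise residual `e = In - beta * Io`.  With `beta` from
#' [linear_prediction_factor()] the residual is orthogonal to the
#' reference (`sum(e * Io)` vanishes to rounding), the normal-equation
#' property of the least-squares slope.
#'
#' @param reference Reference image `Io`.
#' @param noisy Noisy image `In`, same dimensions.
#' @param beta Scalar weight, or a `prediction_factor`.
#' @return Residual matrix.
#' @export
prediction_error <- function(reference, noisy, beta) {
  io <- pixels_of(reference)
  im <- pixels_of(noisy)
  if (!identical(dim(io), dim(im))) {
    stop("shape mismatch between reference and noisy image", call. = FALSE)
  }
  if (inherits(beta, "prediction_factor")) beta <- beta$beta
  im - beta * io
}
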