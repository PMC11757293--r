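#' Two-dimensional intensity grid
#'
#' The basic container used throughout the package: a numeric matrix of
#' pixel intensities together with the dynamic range `L` of the scale the
#' intensities live on (`L = 255` for 8-bit data, `L = 1` for images
#' normalized to `[0, 1]`).  `L` matters only when quality metrics are
#' computed; the transform and shrinkage code is scale-agnostic.
#'
#' @param pixels Numeric matrix of finite intensities.
#' @param dynamic_range Positive scalar, the nominal peak intensity `L`.
#' @return An object of class `image_grid`: a list with elements
#'   `pixels` (matrix), `height`, `width` and `L`.
#' @examples
#' img <- image_grid(matrix(runif(64), 8, 8), dynamic_range = 1)
#' dim(img)
#' @export
image_grid <- function(pixels, dynamic_range = 1) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) {
    stop("all pixel intensities must be finite", call. = FALSE)
  }
  if (!is.numeric(dynamic_range) || length(dynamic_range) != 1L ||
      !is.finite(dynamic_range) || dynamic_range <= 0) {
    stop("`dynamic_range` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width  = ncol(pixels),
      L      = as.numeric(dynamic_range)
    ),
    class = "image_grid"
  )
}

#' @export
dim.image_grid <- function(x) c(x$height, x$width)

#' @export
as.matrix.image_grid <- function(x, ...) x$pixels

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid> %d x %d, dynamic range L = %g, intensities in [%.4g, %.4g]\n",
    x$height, x$width, x$L, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Coerce a matrix or image_grid to an image_grid
#'
#' @param x Matrix or `image_grid`.
#' @param dynamic_range Dynamic range to attach when `x` is a bare matrix;
#'   ignored when `x` is already an `image_grid`.
#' @return An `image_grid`.
#' @export
as_image_grid <- function(x, dynamic_range = 1) {
  if (inherits(x, "image_grid")) x else image_grid(x, dynamic_range)
}

# internal: accept matrix or image_grid, return the pixel matrix
pixels_of <- function(x) {
  if (inherits(x, "image_grid")) x$pixels else as.matrix(x)
}

# internal: run code with a temporary RNG state seeded by `seed`;
# restores the caller's .Random.seed (or its absence) on exit
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
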