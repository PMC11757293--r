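#' @title Multilevel 2-D discrete wavelet transform
#' @description
#' Separable 2-D DWT with symmetric (half-sample) boundary extension,
#' the common default for biorthogonal bases.  A signal of length `n`
#' filtered with a `p`-tap filter yields `floor((n + p - 1) / 2)`
#' coefficients per subband; this slight redundancy is what makes the
#' transform perfectly invertible for arbitrary sizes and boundary
#' handling.  Coefficients agree with the standard MATLAB/PyWavelets
#' `mode='symmetric'` convention to machine precision.
#' @name dwt2d
NULL

# symmetric (half-sample) extension index map: positions
# -(k) .. n+k-1 (0-based) folded back into 1..n, whole-period reflection
sym_ext_index <- function(n, k) {
  i <- (-k):(n + k - 1L)
  i <- i %% (2L * n)
  i <- ifelse(i < n, i, 2L * n - 1L - i)
  i + 1L
}

# analysis step along the row axis of `mat` (each column is a signal);
# returns floor((n + p - 1)/2) rows
dwt_axis0 <- function(mat, filt) {
  n <- nrow(mat)
  p <- length(filt)
  ext <- mat[sym_ext_index(n, p - 1L), , drop = FALSE]
  K <- (n + p - 1L) %/% 2L
  out <- matrix(0, K, ncol(mat))
  base <- 2L * seq_len(K)            # valid-convolution rows kept
  for (j in seq_len(p)) {
    if (filt[j] != 0) {
      out <- out + filt[j] * ext[base + p - j, , drop = FALSE]
    }
  }
  out
}

# synthesis step along the row axis: upsample, filter, crop to out_len rows
idwt_axis0 <- function(ca, cd, lo, hi, out_len) {
  if (!identical(dim(ca), dim(cd))) {
    stop("approximation and detail subbands have inconsistent shapes",
         call. = FALSE)
  }
  N <- nrow(ca)
  p <- length(lo)
  full_len <- 2L * N - p + 2L
  if (full_len < out_len) {
    stop("subband too short to reconstruct the requested length", call. = FALSE)
  }
  nc <- ncol(ca)
  # upsampled coefficient rows (odd rows, 1-based), zero-padded p-1 both ends
  up_a <- matrix(0, 2L * N + 2L * (p - 1L), nc)
  up_d <- up_a
  up_a[2L * seq_len(N) - 1L + (p - 1L), ] <- ca
  up_d[2L * seq_len(N) - 1L + (p - 1L), ] <- cd
  keep <- min(full_len, out_len)
  m <- (p - 1L):(p - 2L + keep)      # 1-based output rows of the full conv
  out <- matrix(0, keep, nc)
  for (j in seq_len(p)) {
    idx <- m - j + 1L + (p - 1L)
    if (lo[j] != 0) out <- out + lo[j] * up_a[idx, , drop = FALSE]
    if (hi[j] != 0) out <- out + hi[j] * up_d[idx, , drop = FALSE]
  }
  out
}

# one 2-D analysis step: returns LL and the three detail orientations.
# HL = highpass along the row axis (horizontal structures), LH = highpass
# along the column axis, HH = diagonal.
dwt2_step <- function(mat, fb) {
  lo0 <- dwt_axis0(mat, fb$dec_lo)
  hi0 <- dwt_axis0(mat, fb$dec_hi)
  list(
    LL = t(dwt_axis0(t(lo0), fb$dec_lo)),
    LH = t(dwt_axis0(t(lo0), fb$dec_hi)),
    HL = t(dwt_axis0(t(hi0), fb$dec_lo)),
    HH = t(dwt_axis0(t(hi0), fb$dec_hi))
  )
}

idwt2_step <- function(ll, det, fb, out_dim) {
  lo0 <- t(idwt_axis0(t(ll), t(det$LH), fb$rec_lo, fb$rec_hi, out_dim[2]))
  hi0 <- t(idwt_axis0(t(det$HL), t(det$HH), fb$rec_lo, fb$rec_hi, out_dim[2]))
  idwt_axis0(lo0, hi0, fb$rec_lo, fb$rec_hi, out_dim[1])
}

#' Decompose an image into a multilevel wavelet pyramid
#'
#' Applies `levels` stages of the separable 2-D DWT to an image.  The
#' approximation of each stage is decomposed further; the three detail
#' orientations (`HL`, `LH`, `HH`) are retained per level.  Level 1 is
#' the finest scale: its `HH` subband carries the diagonal detail used
#' for robust noise estimation (see [estimate_sigma()]).
#'
#' @param image An `image_grid` or numeric matrix.
#' @param wavelet Wavelet name, see [wavelet_filters()]. Default `"bior3.9"`.
#' @param levels Number of decomposition levels (>= 1). The image must
#'   satisfy `min(dim) >= 2^levels`.
#' @return A `wavelet_pyramid`: list with `wavelet`, `levels`, `approx`
#'   (coarsest approximation matrix), `details` (list, level 1 = finest,
#'   each a list of matrices `HL`, `LH`, `HH`), `shapes` (input
#'   dimensions per level, needed for exact inversion) and
#'   `dynamic_range` (carried over from the image).
#' @seealso [reconstruct()], [map_details()]
#' @examples
#' img <- image_grid(matrix(rnorm(64 * 64), 64, 64))
#' pyr <- decompose(img, "bior3.9", levels = 3)
#' max(abs(as.matrix(reconstruct(pyr)) - as.matrix(img)))  # ~1e-15
#' @export
decompose <- function(image, wavelet = "bior3.9", levels = 3L) {
  img <- as_image_grid(image)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1L) {
    stop("`levels` must be an integer >= 1", call. = FALSE)
  }
  if (min(dim(img)) < 2^levels) {
    stop(sprintf(
      "image of size %dx%d is too small for %d decomposition levels (need min dim >= %d)",
      img$height, img$width, levels, 2^levels
    ), call. = FALSE)
  }
  fb <- wavelet_filters(wavelet)
  a <- img$pixels
  details <- vector("list", levels)
  shapes <- vector("list", levels)
  for (j in seq_len(levels)) {
    shapes[[j]] <- dim(a)
    s <- dwt2_step(a, fb)
    details[[j]] <- s[c("HL", "LH", "HH")]
    a <- s$LL
  }
  structure(
    list(wavelet = fb$name, levels = levels, approx = a,
         details = details, shapes = shapes, dynamic_range = img$L),
    class = "wavelet_pyramid"
  )
}

#' Reconstruct an image from a wavelet pyramid
#'
#' Exact inverse of [decompose()] when the coefficients are unmodified
#' (round-trip error at machine precision).
#'
#' @param pyramid A `wavelet_pyramid`.
#' @return An `image_grid` with the source image's dimensions and
#'   dynamic range.
#' @export
reconstruct <- function(pyramid) {
  if (!inherits(pyramid, "wavelet_pyramid")) {
    stop("`pyramid` must be a wavelet_pyramid", call. = FALSE)
  }
  fb <- wavelet_filters(pyramid$wavelet)
  a <- pyramid$approx
  for (j in rev(seq_len(pyramid$levels))) {
    det <- pyramid$details[[j]]
    if (!identical(dim(det$HL), dim(det$LH)) ||
        !identical(dim(det$HL), dim(det$HH)) ||
        !identical(dim(a), dim(det$HL))) {
      stop(sprintf("inconsistent subband shapes at level %d", j), call. = FALSE)
    }
    a <- idwt2_step(a, det, fb, pyramid$shapes[[j]])
  }
  image_grid(a, pyramid$dynamic_range)
}

#' Transform the detail coefficients of a pyramid
#'
#' Applies an elementwise rule (typically a shrinkage function) to every
#' detail subband; the approximation is never touched.  This is the
#' plumbing that lifts the pointwise shrinkage rules over a whole
#' decomposition.
#'
#' @param pyramid A `wavelet_pyramid`.
#' @param rule A vectorized function of the coefficients. When
#'   `per_level = TRUE` it is called as `rule(w, level)` with the level
#'   index `j` (1 = finest).
#' @param per_level Pass the level index to `rule`?
#' @return A new `wavelet_pyramid` with transformed details.
#' @export
map_details <- function(pyramid, rule, per_level = FALSE) {
  if (!inherits(pyramid, "wavelet_pyramid")) {
    stop("`pyramid` must be a wavelet_pyramid", call. = FALSE)
  }
  out <- pyramid
  for (j in seq_len(pyramid$levels)) {
    for (sb in c("HL", "LH", "HH")) {
      w <- pyramid$details[[j]][[sb]]
      v <- if (per_level) rule(w, j) else rule(w)
      if (!is.numeric(v) || !identical(dim(v), dim(w))) {
        stop(sprintf("rule returned a malformed result for subband %s at level %d",
                     sb, j), call. = FALSE)
      }
      if (!all(is.finite(v))) {
        stop(sprintf("rule produced non-finite coefficients in subband %s at level %d",
                     sb, j), call. = FALSE)
      }
      out$details[[j]][[sb]] <- v
    }
  }
  out
}

#' Extract one detail subband
#'
#' @param pyramid A `wavelet_pyramid`.
#' @param level Level index (1 = finest).
#' @param orientation One of `"HL"`, `"LH"`, `"HH"`.
#' @return The coefficient matrix.
#' @export
detail_subband <- function(pyramid, level = 1L, orientation = "HH") {
  if (!inherits(pyramid, "wavelet_pyramid")) {
    stop("`pyramid` must be a wavelet_pyramid", call. = FALSE)
  }
  orientation <- match.arg(orientation, c("HL", "LH", "HH"))
  if (level < 1L || level > pyramid$levels) {
    stop(sprintf("level %d outside 1..%d", level, pyramid$levels), call. = FALSE)
  }
  pyramid$details[[level]][[orientation]]
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat(sprintf("<wavelet_pyramid> %s, %d level(s)\n", x$wavelet, x$levels))
  for (j in seq_len(x$levels)) {
    d <- dim(x$details[[j]]$HH)
    cat(sprintf("  level %d: detail subbands %d x %d\n", j, d[1], d[2]))
  }
  d <- dim(x$approx)
  cat(sprintf("  approx : %d x %d\n", d[1], d[2]))
  invisible(x)
}
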