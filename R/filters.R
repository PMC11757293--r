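#' Biorthogonal spline wavelet filter banks
#'
#' Constructs the four-filter bank (analysis/synthesis low/high pass) for
#' the Cohen-Daubechies-Feauveau biorthogonal spline family `biorNr.Nd`
#' with odd `Nr` and `Nd` (which includes the default `bior3.9`), and for
#' the orthogonal Haar basis.  The filters are derived in closed form:
#' the synthesis scaling filter is the binomial B-spline filter of order
#' `Nr`, and the analysis scaling filter multiplies the spline lowpass
#' `cos^Nd(omega/2)` by the half-band completion polynomial
#' `sum_{n=0}^{L-1} C(L-1+n, n) sin^{2n}(omega/2)`, `L = (Nr + Nd) / 2`.
#' Highpass filters follow by the alternating-sign (quadrature mirror)
#' relation.  Coefficients agree with the standard published filter
#' banks (e.g. MATLAB's and PyWavelets' `bior3.9`) to machine precision.
#'
#' @param name Wavelet identifier: `"haar"` or `"biorNr.Nd"` with odd
#'   `Nr >= 1`, odd `Nd >= Nr` (e.g. `"bior3.9"`).
#' @return A list of class `wavelet_filters` with elements `name`,
#'   `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` (numeric vectors, all the
#'   same length) and `length` (the common filter length).
#' @examples
#' fb <- wavelet_filters("bior3.9")
#' fb$length  # 20 taps
#' @export
wavelet_filters <- function(name = "bior3.9") {
  if (!is.character(name) || length(name) != 1L) {
    stop("wavelet name must be a single string", call. = FALSE)
  }
  if (identical(name, "haar")) {
    s <- 1 / sqrt(2)
    return(structure(
      list(
        name = "haar",
        dec_lo = c(s, s), dec_hi = c(-s, s),
        rec_lo = c(s, s), rec_hi = c(s, -s),
        length = 2L
      ),
      class = "wavelet_filters"
    ))
  }
  m <- regmatches(name, regexec("^bior([0-9]+)\\.([0-9]+)$", name))[[1]]
  if (length(m) != 3L) {
    stop(sprintf("unknown wavelet '%s' (supported: haar, biorNr.Nd with odd Nr, Nd)", name),
         call. = FALSE)
  }
  nr <- as.integer(m[2]); nd <- as.integer(m[3])
  if (nr %% 2L == 0L || nd %% 2L == 0L || nd < nr) {
    stop(sprintf("unsupported bior order %d.%d: need odd Nr, odd Nd, Nd >= Nr", nr, nd),
         call. = FALSE)
  }

  # synthesis scaling filter: binomial spline, sqrt(2) * C(Nr, k) / 2^Nr
  rec_lo_short <- sqrt(2) * choose(nr, 0:nr) / 2^nr

  # analysis scaling filter via the CDF completion polynomial.
  # Work with Laurent polynomials in y = exp(i*omega/2), stored as
  # coefficient vectors on a symmetric integer power grid.
  pconv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      idx <- i:(i + length(b) - 1L)
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  ppow <- function(p, k) {
    r <- 1
    for (i in seq_len(k)) r <- pconv(r, p)
    r
  }
  cosw2 <- c(0.5, 0, 0.5)              # cos(omega/2): powers -1, +1
  sin2  <- c(-0.25, 0, 0.5, 0, -0.25)  # sin^2(omega/2): powers -2..+2
  L <- (nr + nd) / 2
  acc <- 1
  if (L > 1) {
    for (n in 1:(L - 1)) {
      term <- choose(L - 1 + n, n) * ppow(sin2, n)
      pad <- (length(term) - length(acc)) / 2
      acc <- c(numeric(pad), acc, numeric(pad)) + term
    }
  }
  poly <- pconv(ppow(cosw2, nd), acc)
  taps <- poly[abs(poly) > 1e-14]      # nonzero taps sit on every other power
  dec_lo <- sqrt(2) * taps / sum(taps) # normalize m0(0) = 1, then sqrt(2)

  p <- length(dec_lo)
  pad <- (p - length(rec_lo_short)) / 2
  rec_lo <- c(numeric(pad), rec_lo_short, numeric(pad))

  # alternating-sign highpass construction (1-based indices)
  k <- seq_len(p)
  dec_hi <- (-1)^k * rec_lo
  rec_hi <- (-1)^(k - 1) * dec_lo

  structure(
    list(name = name, dec_lo = dec_lo, dec_hi = dec_hi,
         rec_lo = rec_lo, rec_hi = rec_hi, length = as.integer(p)),
    class = "wavelet_filters"
  )
}

#' @export
print.wavelet_filters <- function(x, ...) {
  cat(sprintf("<wavelet_filters> %s, %d taps per filter\n", x$name, x$length))
  invisible(x)
}
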