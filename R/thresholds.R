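#' Robust noise level estimate from the finest diagonal subband
#'
#' Median absolute deviation estimator `sigma = median(|w|) / 0.6745`
#' computed over the `HH` subband at level 1, the standard robust
#' estimate of the standard deviation of additive Gaussian noise in the
#' wavelet domain (the detail coefficients of the noise-free image are
#' sparse there, so the median is driven by the noise floor).
#'
#' @param hh1 Coefficient matrix (typically
#'   `detail_subband(pyr, 1, "HH")`) or a `wavelet_pyramid`, in which
#'   case its finest `HH` subband is used.
#' @return A `noise_estimate`: list with `sigma` (>= 0) and `source`
#'   (`"HH1-median"`).
#' @examples
#' estimate_sigma(matrix(c(1, -1), 4, 4))$sigma  # 1 / 0.6745
#' @export
estimate_sigma <- function(hh1) {
  if (inherits(hh1, "wavelet_pyramid")) {
    hh1 <- detail_subband(hh1, 1L, "HH")
  }
  w <- as.numeric(pixels_of(hh1))
  if (length(w) == 0L) stop("empty coefficient grid", call. = FALSE)
  if (!all(is.finite(w))) stop("coefficients must be finite", call. = FALSE)
  structure(
    list(sigma = stats::median(abs(w)) / 0.6745, source = "HH1-median"),
    class = "noise_estimate"
  )
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %g (%s)\n", x$sigma, x$source))
  invisible(x)
}

# internal: resolve log base option to a log function
log_fun <- function(log_base = c("natural", "ten")) {
  log_base <- match.arg(log_base)
  if (log_base == "natural") log else log10
}

as_sigma <- function(sigma) {
  if (inherits(sigma, "noise_estimate")) sigma <- sigma$sigma
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be a single finite number >= 0", call. = FALSE)
  }
  sigma
}

#' Universal (VisuShrink) threshold
#'
#' `T = sigma * sqrt(2 * log(N))`, the Donoho-Johnstone global
#' threshold.  `N` is the length of the input signal; by the package's
#' convention this is the total number of pixels of the image being
#' denoised (a per-subband count can be passed instead if desired).
#'
#' @param sigma Noise standard deviation (or a `noise_estimate`).
#' @param n_pixels Signal length `N` (>= 2).
#' @param log_base `"natural"` (default, the classical convention) or
#'   `"ten"`.
#' @return Threshold value `T >= 0`.
#' @export
universal_threshold <- function(sigma, n_pixels, log_base = "natural") {
  sigma <- as_sigma(sigma)
  if (!is.numeric(n_pixels) || length(n_pixels) != 1L || n_pixels < 2) {
    stop("`n_pixels` must be a single number >= 2", call. = FALSE)
  }
  lg <- log_fun(log_base)
  sigma * sqrt(2 * lg(n_pixels))
}

#' BayesShrink per-subband threshold
#'
#' `T = sigma^2 / sigma_x` where `sigma_x = sqrt(max(sigma_y^2 -
#' sigma^2, 0))` and `sigma_y^2` is the mean of the squared subband
#' coefficients: the threshold minimizing Bayesian risk under a
#' generalized-Gaussian prior on the clean coefficients.  When the
#' signal variance estimate vanishes (`sigma_y^2 <= sigma^2`) the
#' subband is judged pure noise and a finite "kill-all" sentinel
#' `T = max(|w|) + 1` is returned so that any shrinkage rule zeroes the
#' whole subband; the sentinel is flagged in the `kill_all` attribute.
#'
#' @param sigma Noise standard deviation (or a `noise_estimate`).
#' @param subband Coefficient matrix of the subband.
#' @return Threshold value with attribute `kill_all` (logical).
#' @export
bayes_threshold <- function(sigma, subband) {
  sigma <- as_sigma(sigma)
  w <- as.numeric(pixels_of(subband))
  if (length(w) == 0L) stop("empty subband", call. = FALSE)
  sig_y2 <- mean(w^2)
  sig_x <- sqrt(max(sig_y2 - sigma^2, 0))
  if (sig_x == 0) {
    return(structure(max(abs(w)) + 1, kill_all = TRUE))
  }
  structure(sigma^2 / sig_x, kill_all = FALSE)
}

#' Level-adaptive threshold weighted by the linear prediction factor
#'
#' Extends the universal threshold with two factors: the decomposition
#' level `j` through `log(1 + j)` (coarser levels carry proportionally
#' more signal energy, so their cutoff grows) and the linear prediction
#' factor `beta` relating the noisy image to a clean reference (see
#' [linear_prediction_factor()]).  Under the default parse the threshold
#' at level `j` is
#'
#' `T_j = sigma * sqrt(2 * log(N)) * log(1 + j) * beta`
#'
#' `eq13_parse = "divide_beta"` instead divides by `beta`; both variants
#' are pure scalings of the universal threshold and are recorded in the
#' result's `parse` attribute.
#'
#' @param sigma Noise standard deviation (or a `noise_estimate`).
#' @param n_pixels Signal length `N` (>= 2).
#' @param level Decomposition level `j >= 1` (1 = finest).
#' @param beta Linear prediction factor (> 0), or a `prediction_factor`.
#' @param log_base `"natural"` (default) or `"ten"`.
#' @param eq13_parse `"product"` (default) or `"divide_beta"`.
#' @return Threshold value with attribute `parse`.
#' @export
proposed_threshold <- function(sigma, n_pixels, level, beta,
                               log_base = "natural",
                               eq13_parse = c("product", "divide_beta")) {
  eq13_parse <- match.arg(eq13_parse)
  if (inherits(beta, "prediction_factor")) beta <- beta$beta
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a single finite number > 0", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level < 1) {
    stop("`level` must be a single integer >= 1", call. = FALSE)
  }
  base_t <- universal_threshold(sigma, n_pixels, log_base)
  lg <- log_fun(log_base)
  scale <- lg(1 + level) * if (eq13_parse == "product") beta else 1 / beta
  structure(base_t * scale, parse = eq13_parse)
}
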