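#' @title Shrinkage rules for detail coefficients
#' @description
#' Pointwise (vectorized) rules mapping a wavelet coefficient `w` and a
#' threshold `T >= 0` to a denoised coefficient.  All rules are odd
#' functions of `w`, non-expansive (`|rule(w)| <= |w|`) and zero below
#' the threshold.
#' @name shrinkage
NULL

check_T <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T < 0) {
    stop("threshold `T` must be a single finite number >= 0", call. = FALSE)
  }
  T
}

#' @describeIn shrinkage Keep-or-kill: `w` if `|w| >= T`, else 0.  The
#'   boundary `|w| = T` is retained.
#' @param w Numeric vector/matrix of coefficients.
#' @param T Threshold (>= 0).
#' @export
shrink_hard <- function(w, T) {
  T <- check_T(T)
  w * (abs(w) >= T)
}

#' @describeIn shrinkage Magnitude reduced by `T` on the kept branch:
#'   `sign(w) * (|w| - T)` if `|w| >= T`, else 0.
#' @export
shrink_soft <- function(w, T) {
  T <- check_T(T)
  sign(w) * pmax(abs(w) - T, 0)
}

#' @describeIn shrinkage Interpolates hard and soft: the kept branch
#'   subtracts `alpha * T`; `alpha = 0` is hard (on the kept branch),
#'   `alpha = 1` is soft.
#' @param alpha Semi-soft interpolation weight in `[0, 1]`.
#' @export
shrink_semisoft <- function(w, T, alpha = 0.5) {
  T <- check_T(T)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single number in [0, 1]", call. = FALSE)
  }
  sign(w) * (abs(w) - alpha * T) * (abs(w) >= T)
}

#' @describeIn shrinkage Continuous sine-tapered rule: on the kept
#'   branch the shrink amount is `sin((pi/2) * (T/|w|)^(beta*T)) * T`,
#'   which equals `T` at `|w| = T` (so the rule is continuous there,
#'   like soft) and decays to zero as `|w|` grows (so large
#'   coefficients pass unchanged, like hard).  `beta` is the linear
#'   prediction factor; the exponent is the product `beta * T`.  With
#'   `T = 0` the rule is the identity.
#' @param beta Taper exponent weight (> 0), or a `prediction_factor`.
#' @export
shrink_adaptive <- function(w, T, beta) {
  T <- check_T(T)
  if (inherits(beta, "prediction_factor")) beta <- beta$beta
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a single finite number > 0", call. = FALSE)
  }
  if (T == 0) return(w)
  out <- w
  out[abs(w) < T] <- 0
  keep <- abs(w) >= T        # kept branch only: never evaluates 0^0
  if (any(keep)) {
    wk <- w[keep]
    taper <- sin((pi / 2) * (T / abs(wk))^(beta * T)) * T
    out[keep] <- sign(wk) * (abs(wk) - taper)
  }
  out
}

#' Build a shrinkage rule closure
#'
#' Packages one of the four rules with its parameters into a one- or
#' two-argument function suitable for [map_details()].  When
#' `threshold` is a function it is called as `threshold(level)` and the
#' returned closure expects the level index (use
#' `map_details(..., per_level = TRUE)`).
#'
#' @param kind One of `"hard"`, `"soft"`, `"semisoft"`, `"adaptive"`.
#' @param threshold Scalar threshold, or a function of the level index.
#' @param alpha Semi-soft weight (used when `kind = "semisoft"`).
#' @param beta Taper weight (required when `kind = "adaptive"`).
#' @return A function of the coefficients (and possibly the level).
#' @export
shrink_rule <- function(kind = c("hard", "soft", "semisoft", "adaptive"),
                        threshold, alpha = 0.5, beta = NULL) {
  kind <- match.arg(kind)
  if (kind == "adaptive" && is.null(beta)) {
    stop("the adaptive rule requires `beta`", call. = FALSE)
  }
  apply_rule <- function(w, T) {
    switch(kind,
      hard     = shrink_hard(w, T),
      soft     = shrink_soft(w, T),
      semisoft = shrink_semisoft(w, T, alpha),
      adaptive = shrink_adaptive(w, T, beta)
    )
  }
  if (is.function(threshold)) {
    function(w, level) apply_rule(w, threshold(level))
  } else {
    T <- check_T(threshold)
    function(w) apply_rule(w, T)
  }
}
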