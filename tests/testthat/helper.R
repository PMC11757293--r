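# shared fixtures built in code

rand_img <- function(n = 64, m = n, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * m), n, m)
}

# read one subband matrix out of the frozen PyWavelets fixture
read_pywt_fixture <- function(subband) {
  fx <- utils::read.csv(test_path("fixtures", "pywt_bior39_8x8.csv"))
  d <- fx[fx$subband == subband, ]
  m <- matrix(NA_real_, max(d$row), max(d$col))
  m[cbind(d$row, d$col)] <- d$value
  m
}

# scalar reference implementations of the shrinkage closed forms,
# written directly from their definitions; the independent oracle the
# vectorized rules are checked against
oracle_hard <- function(w, T) if (abs(w) >= T) w else 0
oracle_soft <- function(w, T) if (abs(w) >= T) sign(w) * (abs(w) - T) else 0
oracle_semisoft <- function(w, T, a) if (abs(w) >= T) sign(w) * (abs(w) - a * T) else 0
oracle_adaptive <- function(w, T, b) {
  if (T == 0) return(w)
  if (abs(w) < T) return(0)
  sign(w) * (abs(w) - sin((pi / 2) * (T / abs(w))^(b * T)) * T)
}
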