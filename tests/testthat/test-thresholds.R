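test_that("sigma estimator matches its closed form and is robustly consistent", {
  # alternating +1/-1 grid: median |w| = 1
  alt <- matrix(c(1, -1), 8, 8)
  est <- estimate_sigma(alt)
  expect_equal(est$sigma, 1 / 0.6745)
  expect_equal(est$source, "HH1-median")

  expect_equal(estimate_sigma(matrix(0, 4, 4))$sigma, 0)

  # Monte-Carlo consistency: MAD/0.6745 on raw Gaussian draws
  set.seed(42)
  g <- matrix(rnorm(256 * 256, 0, 0.05), 256, 256)
  expect_lt(abs(estimate_sigma(g)$sigma - 0.05) / 0.05, 0.05)

  # invariance to sign flips and permutations
  set.seed(7)
  w <- matrix(rnorm(100), 10, 10)
  s0 <- estimate_sigma(w)$sigma
  expect_equal(estimate_sigma(-w)$sigma, s0)
  expect_equal(estimate_sigma(matrix(sample(w), 10, 10))$sigma, s0)

  expect_error(estimate_sigma(matrix(numeric(0), 0, 0)), "empty")
})

test_that("universal threshold follows T = sigma * sqrt(2 log N)", {
  expect_equal(universal_threshold(0, 1e6), 0)
  expect_equal(universal_threshold(1, exp(2)), 2)
  # frozen arithmetic: sigma from the alternating-grid example, N = 4096
  sig <- 1 / 0.6745
  expect_equal(universal_threshold(sig, 4096), sig * sqrt(2 * log(4096)))
  expect_equal(universal_threshold(1, 100, log_base = "ten"), sqrt(2 * 2))
  # homogeneity of degree 1 in sigma
  for (s in c(0.1, 1, 7)) {
    expect_equal(universal_threshold(3 * s, 512), 3 * universal_threshold(s, 512))
  }
  expect_error(universal_threshold(1, 1), ">= 2")
  expect_error(universal_threshold(-1, 10), ">= 0")
})

test_that("bayes threshold matches sigma^2 / sigma_x with the kill-all sentinel", {
  # mean square 5, sigma^2 = 1 -> sigma_x = 2, T = 1/2
  sb <- matrix(sqrt(5), 3, 3)
  expect_equal(as.numeric(bayes_threshold(1, sb)), 0.5)
  expect_false(attr(bayes_threshold(1, sb), "kill_all"))

  # mean square below sigma^2: subband judged pure noise
  sb2 <- matrix(sqrt(0.5), 4, 4)
  t2 <- bayes_threshold(1, sb2)
  expect_true(attr(t2, "kill_all"))
  expect_gt(as.numeric(t2), max(abs(sb2)))

  # no noise, no shrinkage
  expect_equal(as.numeric(bayes_threshold(0, matrix(1:4, 2))), 0)

  # oracle equivalence on random subbands with signal variance present
  set.seed(11)
  for (i in 1:100) {
    w <- matrix(rnorm(64, sd = runif(1, 1, 3)), 8, 8)
    sig <- runif(1, 0, 0.5)
    ms <- mean(w^2)
    if (ms > sig^2) {
      expect_equal(as.numeric(bayes_threshold(sig, w)),
                   sig^2 / sqrt(ms - sig^2))
    }
  }
  expect_error(bayes_threshold(1, matrix(numeric(0), 0, 0)), "empty")
})

test_that("level-adaptive threshold scales the universal threshold as specified", {
  expect_equal(as.numeric(proposed_threshold(0, 100, 1, 1)), 0)
  # sigma = 1, N = e^2, j = 1, beta = 1 -> 2 * ln 2
  expect_equal(as.numeric(proposed_threshold(1, exp(2), 1, 1)), 2 * log(2))
  # strictly increasing in the level under the product parse
  ts <- vapply(1:5, function(j) {
    as.numeric(proposed_threshold(0.3, 4096, j, 0.8))
  }, numeric(1))
  expect_true(all(diff(ts) > 0))
  # consistency anchor: log(1+j) = 1 and beta = 1 recovers the universal value
  expect_equal(as.numeric(proposed_threshold(2, 1024, exp(1) - 1, 1)),
               universal_threshold(2, 1024))
  # divide_beta parse is the reciprocal scaling
  expect_equal(as.numeric(proposed_threshold(1, 100, 2, 4, eq13_parse = "divide_beta")),
               as.numeric(proposed_threshold(1, 100, 2, 1)) / 4)
  expect_equal(attr(proposed_threshold(1, 100, 1, 1), "parse"), "product")

  expect_error(proposed_threshold(1, 100, 1, 0), "> 0")
  expect_error(proposed_threshold(1, 100, 0, 1), ">= 1")
})
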