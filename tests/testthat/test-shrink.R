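test_that("hard, soft and semi-soft rules match their closed forms", {
  expect_equal(shrink_hard(5, 3), 5)
  expect_equal(shrink_hard(-2, 3), 0)
  expect_equal(shrink_hard(3, 3), 3)     # boundary retained

  expect_equal(shrink_soft(-5, 3), -2)
  expect_equal(shrink_soft(3, 3), 0)
  expect_equal(shrink_soft(0.5, 3), 0)

  expect_equal(shrink_semisoft(-5, 3, 0.5), -3.5)
  expect_equal(shrink_semisoft(5, 3, 0), 5)    # hard limit
  expect_equal(shrink_semisoft(5, 3, 1), 2)    # soft limit
  expect_error(shrink_semisoft(1, 1, 1.5), "\\[0, 1\\]")
})

test_that("adaptive rule matches its closed form and is continuous at T", {
  expect_equal(shrink_adaptive(1, 1, 1), 0)
  expect_equal(shrink_adaptive(2, 1, 1), 2 - sqrt(2) / 2)
  expect_equal(shrink_adaptive(0.5, 1, 1), 0)
  expect_equal(shrink_adaptive(c(-3, 0, 3), 0, 2), c(-3, 0, 3))  # T = 0: identity
  expect_error(shrink_adaptive(1, 1, 0), "> 0")

  for (T in c(0.1, 1, 10)) {
    for (b in c(0.5, 1, 2)) {
      expect_lt(abs(shrink_adaptive(T * (1 + 1e-9), T, b)), 1e-6 * T)
    }
  }
})

test_that("vectorized rules are bit-identical to the pointwise definitions", {
  set.seed(123)
  w <- c(seq(-20, 20, length.out = 10000), 0)
  T <- 2.3; a <- 0.37; b <- 0.8
  expect_identical(shrink_hard(w, T), vapply(w, oracle_hard, numeric(1), T = T))
  expect_identical(shrink_soft(w, T), vapply(w, oracle_soft, numeric(1), T = T))
  expect_identical(shrink_semisoft(w, T, a),
                   vapply(w, oracle_semisoft, numeric(1), T = T, a = a))
  expect_identical(shrink_adaptive(w, T, b),
                   vapply(w, oracle_adaptive, numeric(1), T = T, b = b))
})

test_that("rules are odd, non-expansive and satisfy the soft<=adaptive<=hard sandwich", {
  w <- seq(-30, 30, length.out = 10001)
  for (T in c(0.5, 2)) {
    for (b in c(0.5, 1, 2)) {
      h <- shrink_hard(w, T); s <- shrink_soft(w, T); ad <- shrink_adaptive(w, T, b)
      expect_equal(shrink_hard(-w, T), -h)
      expect_equal(shrink_soft(-w, T), -s)
      expect_equal(shrink_adaptive(-w, T, b), -ad)
      expect_equal(shrink_semisoft(-w, T, 0.3), -shrink_semisoft(w, T, 0.3))
      expect_true(all(abs(h) <= abs(w) + 1e-12))
      expect_true(all(abs(s) <= abs(w) + 1e-12))
      expect_true(all(abs(ad) <= abs(w) + 1e-12))
      expect_true(all(abs(s) <= abs(ad) + 1e-12))
      expect_true(all(abs(ad) <= abs(h) + 1e-12))
      expect_true(all(sign(ad) * sign(w) >= 0))
    }
  }
})

test_that("adaptive rule converges monotonically to the identity away from T", {
  for (T in c(0.5, 1, 5)) {
    for (b in c(0.5, 1)) {
      k <- 2:100
      gap <- k * T - shrink_adaptive(k * T, T, b)
      expect_true(all(gap > 0))
      expect_true(all(diff(gap) < 0))
      expect_lt(gap[length(gap)], gap[1] / 2)
    }
  }
})

test_that("shrink_rule lifts the pointwise rules without changing them", {
  set.seed(4)
  w <- matrix(rnorm(64, sd = 3), 8, 8)
  expect_identical(shrink_rule("soft", 1.2)(w), shrink_soft(w, 1.2))
  expect_identical(shrink_rule("adaptive", 1.2, beta = 0.7)(w),
                   shrink_adaptive(w, 1.2, 0.7))
  lev_rule <- shrink_rule("hard", function(j) j * 0.5)
  expect_identical(lev_rule(w, 2), shrink_hard(w, 1.0))
  expect_error(shrink_rule("adaptive", 1), "requires `beta`")
})
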