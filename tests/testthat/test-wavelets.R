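test_that("single-level decomposition reproduces the independent oracle", {
  # fixture: dwt2 of a fixed 8x8 image computed by PyWavelets
  # (bior3.9, symmetric mode), frozen to text
  img <- read_pywt_fixture("img")
  pyr <- decompose(img, "bior3.9", levels = 1)
  expect_equal(pyr$approx, read_pywt_fixture("cA"), tolerance = 1e-12)
  expect_equal(detail_subband(pyr, 1, "HL"), read_pywt_fixture("cH"), tolerance = 1e-12)
  expect_equal(detail_subband(pyr, 1, "LH"), read_pywt_fixture("cV"), tolerance = 1e-12)
  expect_equal(detail_subband(pyr, 1, "HH"), read_pywt_fixture("cD"), tolerance = 1e-12)
})

test_that("round trip is the identity for random, zero and constant images", {
  for (s in 1:10) {
    x <- rand_img(64, seed = s)
    err <- max(abs(as.matrix(reconstruct(decompose(x, "bior3.9", 3))) - x))
    expect_lt(err, 1e-8 * max(abs(x)))
  }
  # non-square, odd dimensions
  y <- rand_img(33, 47, seed = 99)
  expect_lt(max(abs(as.matrix(reconstruct(decompose(y, "bior3.9", 2))) - y)), 1e-10)

  z <- matrix(0, 64, 64)
  pz <- decompose(z, "bior3.9", 3)
  expect_equal(max(abs(pz$approx)), 0)
  for (j in 1:3) expect_equal(max(abs(detail_subband(pz, j, "HH"))), 0)

  cst <- matrix(100, 64, 64)
  pc <- decompose(cst, "bior3.9", 1)
  expect_lt(max(abs(detail_subband(pc, 1, "HH"))), 1e-8)
  expect_lt(max(abs(detail_subband(pc, 1, "HL"))), 1e-8)
  expect_equal(as.matrix(reconstruct(pc)), cst, tolerance = 1e-12)
})

test_that("the transform is linear, coefficientwise", {
  x <- rand_img(32, seed = 5)
  y <- rand_img(32, seed = 6)
  a <- 2.5; b <- -1.25
  p_lin <- decompose(a * x + b * y, "bior3.9", 2)
  px <- decompose(x, "bior3.9", 2)
  py <- decompose(y, "bior3.9", 2)
  expect_equal(p_lin$approx, a * px$approx + b * py$approx, tolerance = 1e-8)
  for (j in 1:2) {
    for (sb in c("HL", "LH", "HH")) {
      expect_equal(detail_subband(p_lin, j, sb),
                   a * detail_subband(px, j, sb) + b * detail_subband(py, j, sb),
                   tolerance = 1e-8)
    }
  }
})

test_that("subband shape bookkeeping is stable across levels 1-4", {
  x <- rand_img(64, seed = 1)
  p <- 20  # bior3.9 filter length
  for (lev in 1:4) {
    pyr <- decompose(x, "bior3.9", lev)
    expect_equal(pyr$levels, lev)
    expect_length(pyr$details, lev)
    n <- 64
    for (j in 1:lev) {
      expect_equal(unname(pyr$shapes[[j]]), c(n, n))
      n <- (n + p - 1) %/% 2
      expect_equal(dim(detail_subband(pyr, j, "HH")), c(n, n))
    }
    expect_equal(dim(pyr$approx), c(n, n))
    expect_lt(max(abs(as.matrix(reconstruct(pyr)) - x)), 1e-10)
  }
})

test_that("decomposition rejects bad inputs explicitly", {
  expect_error(decompose(rand_img(7, seed = 1), "bior3.9", 3), "too small")
  expect_error(decompose(rand_img(64, seed = 1), "bior3.9", 0), ">= 1")
  expect_error(decompose(rand_img(64, seed = 1), "waveletX", 2), "unknown wavelet")
  expect_error(decompose(matrix(c(1, NA, 3, 4), 2), "haar", 1), "finite")
})

test_that("reconstruct rejects structurally broken pyramids", {
  pyr <- decompose(rand_img(32, seed = 2), "bior3.9", 1)
  broken <- pyr
  broken$details[[1]]$HH <- broken$details[[1]]$HH[-1, ]
  expect_error(reconstruct(broken), "inconsistent subband shapes")
})

test_that("map_details transforms only the details, with level awareness", {
  x <- rand_img(48, seed = 3)
  pyr <- decompose(x, "bior3.9", 2)

  expect_equal(map_details(pyr, identity), pyr)

  zeroed <- map_details(pyr, function(w) w * 0)
  expect_equal(zeroed$approx, pyr$approx)
  approx_only <- reconstruct(zeroed)
  # linearity oracle: details-only + approx-only reconstructions add up
  doubled <- reconstruct(map_details(pyr, function(w) 2 * w))
  full <- reconstruct(pyr)
  expect_equal(as.matrix(doubled),
               2 * as.matrix(full) - as.matrix(approx_only),
               tolerance = 1e-10)

  lev_seen <- integer(0)
  out <- map_details(pyr, function(w, j) { lev_seen <<- c(lev_seen, j); w + j },
                     per_level = TRUE)
  expect_equal(sort(unique(lev_seen)), 1:2)
  expect_equal(detail_subband(out, 2, "HH"), detail_subband(pyr, 2, "HH") + 2)

  expect_error(map_details(pyr, function(w) w * NA_real_), "non-finite")
  expect_error(map_details(pyr, function(w) w[-1]), "malformed")
})
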