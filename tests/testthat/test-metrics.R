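test_that("MSE matches its definition and is symmetric", {
  x <- matrix(0, 2, 2)
  y <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(matrix(0, 3, 3), matrix(255, 3, 3)), 65025)
  expect_equal(mse(x, y), 7.5)
  expect_equal(mse(x, y), mse(y, x))
  expect_error(mse(x, matrix(0, 3, 3)), "shape mismatch")
})

test_that("PSNR identities hold, including the printed-table cross-check", {
  x <- matrix(runif(16), 4)
  expect_equal(psnr(x, x, 255), Inf)
  # MSE = L^2 -> 0 dB
  expect_equal(psnr(matrix(0, 2, 2), matrix(255, 2, 2), 255), 0)
  # internal arithmetic consistency of the PSNR formula with the
  # benchmark pairing MSE = 29 <-> PSNR = 33.55 dB (8-bit scale)
  expect_equal(10 * log10(255^2 / 29), 33.55, tolerance = 0.05 / 33.55)
  y <- x + 0.1
  expect_equal(psnr(x, y, 255), 10 * log10(255^2 / mse(x, y)))
  expect_error(psnr(x, x, 0), "positive")
})

test_that("global SSIM follows the single-window formula", {
  x <- matrix(runif(64), 8)
  expect_equal(ssim(x, x, 255), 1)
  expect_equal(ssim(x, x, 1, mode = "windowed"), 1)

  # constant images 0 vs 255: only the luminance term survives
  C1 <- (0.01 * 255)^2
  expect_equal(ssim(matrix(0, 4, 4), matrix(255, 4, 4), 255), C1 / (255^2 + C1))

  # anti-correlated zero-mean images drive the structure term negative
  set.seed(21)
  z <- matrix(rnorm(256, 0, 50), 16, 16)
  z <- z - mean(z)
  expect_lt(ssim(z, -z, 255), 0)

  # symmetry
  set.seed(22)
  a <- matrix(runif(100, 0, 255), 10)
  b <- matrix(runif(100, 0, 255), 10)
  expect_equal(ssim(a, b, 255), ssim(b, a, 255))
  expect_true(all(abs(c(ssim(a, b, 255), ssim(a, b, 255, mode = "windowed"))) <= 1))
})

test_that("PSNR strictly decreases as the injected noise variance grows", {
  clean <- brain_phantom(64, seed = 8)
  for (s in 1:10) {
    p <- vapply(c(0.01, 0.02, 0.03, 0.04, 0.05), function(v) {
      noisy <- add_gaussian_noise(clean, v, seed = 1000 + s)
      psnr(255 * as.matrix(clean), 255 * as.matrix(noisy), 255)
    }, numeric(1))
    expect_true(all(diff(p) < 0))
  }
})

test_that("metrics_report rescales normalized images to the reporting range", {
  clean <- brain_phantom(48, seed = 2)
  noisy <- add_gaussian_noise(clean, 0.01, seed = 3)
  rep_ <- metrics_report(clean, noisy)
  expect_s3_class(rep_, "metrics_report")
  expect_equal(rep_$mse, mse(255 * as.matrix(clean), 255 * as.matrix(noisy)))
  expect_equal(rep_$L, 255)
  same <- metrics_report(clean, clean)
  expect_equal(same$mse, 0)
  expect_equal(same$psnr_db, Inf)
  expect_equal(same$ssim, 1)
})
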