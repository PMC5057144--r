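# Histograms, resolution estimation, SNR scaling.

test_that("histograms count every pixel into 0-aligned bins", {
  const <- matrix(4.32, 50, 40)
  h <- attenuation_histogram(const)
  expect_equal(sum(h$bins$count), length(const))
  expect_equal(sum(h$bins$count > 0), 1)
  hit <- h$bins[h$bins$count > 0, ]
  expect_lte(hit$bin_lo, 4.32); expect_gt(hit$bin_hi, 4.32)
  # bin edges are aligned to 0.0
  expect_equal(hit$bin_lo, round(hit$bin_lo / 0.1) * 0.1, tolerance = 1e-9)

  p <- small_phantom(seed = 2)
  roi <- rbind(c(10, 80), c(10, 80))  # pixel width 1 for a raw matrix
  h2 <- attenuation_histogram(p$volume$data[, , 10], roi = roi, bin_width = 0.1)
  expect_equal(h2$n_pixels, sum(h2$bins$count))
  expect_error(attenuation_histogram(p$volume, roi = rbind(c(-10, 50))),
               class = "axotomo_argument_error")
  expect_error(attenuation_histogram(const, bin_width = 0),
               class = "axotomo_argument_error")
})

test_that("histograms are invariant under joint image+ROI translation", {
  set.seed(11)
  img <- matrix(runif(120 * 120, 0, 8), 120)
  attr(img, "pixel_width") <- 1
  roi1 <- rbind(c(30, 80), c(35, 85))
  shifted <- img[c(21:120, 1:20), c(16:120, 1:15)]  # shift by (-20, -15)
  attr(shifted, "pixel_width") <- 1
  roi2 <- roi1 - cbind(c(20, 15), c(20, 15))
  h1 <- attenuation_histogram(img, roi1)
  h2 <- attenuation_histogram(shifted, roi2)
  expect_equal(h1$bins, h2$bins)
})

test_that("resolution estimation recovers imposed blurs and fails on noise", {
  vw <- 2.76
  set.seed(99)
  src <- matrix(rnorm(256 * 256), 256)
  for (fwhm_px in c(4, 8)) {
    img <- gaussian_blur(src, fwhm_px / 2.355) +
      matrix(rnorm(256 * 256, 0, 0.03), 256)
    est <- estimate_resolution_fourier(img, pixel_width = vw)
    expect_equal(est$status, "ok")
    true_um <- fwhm_px * vw
    expect_gt(est$resolution, true_um / 1.5)
    expect_lt(est$resolution, true_um * 1.5)
  }
  wn <- matrix(rnorm(128 * 128), 128)
  fail <- estimate_resolution_fourier(wn, vw)
  expect_identical(fail$status, "no_signal")
  expect_true(is.na(fail$resolution))
  expect_error(estimate_resolution_fourier(matrix(0, 32, 32)),
               class = "axotomo_argument_error")
})

test_that("the resolution estimate is monotone in blur and scale-invariant", {
  p <- small_phantom(seed = 2)
  sl <- p$volume$data[, , 24]
  set.seed(5)
  noise <- matrix(rnorm(length(sl), 0, 0.02), nrow(sl))
  e4 <- estimate_resolution_fourier(gaussian_blur(sl, 4 / 2.355) + noise, 2.76)
  e8 <- estimate_resolution_fourier(gaussian_blur(sl, 8 / 2.355) + noise, 2.76)
  expect_gt(e8$resolution, e4$resolution)
  img <- gaussian_blur(sl, 2) + noise
  a <- estimate_resolution_fourier(img, 2.76)
  b <- estimate_resolution_fourier(img * 7.5, 2.76)
  expect_equal(a$resolution, b$resolution, tolerance = 1e-9)
})

test_that("SNR scales as the 3/2 power of voxel width", {
  s <- snr_scaling(c(1, 2, 4, 8), photons_per_um3 = 20, n_samples = 2e4,
                   seed = 3)
  expect_lt(abs(s$exponent - 1.5), 3 * s$std_error)
  expect_error(snr_scaling(c(1, 2, 4), no_noise = TRUE),
               class = "axotomo_degenerate_error")
  expect_error(snr_scaling(c(1, 2)), class = "axotomo_argument_error")
})

test_that("doubling the flux shifts the intercept by log sqrt(2), not the exponent", {
  s1 <- snr_scaling(c(1, 2, 4, 8), photons_per_um3 = 20, n_samples = 5e4,
                    seed = 3)
  s2 <- snr_scaling(c(1, 2, 4, 8), photons_per_um3 = 40, n_samples = 5e4,
                    seed = 3)
  expect_lt(abs(s1$exponent - s2$exponent), 3 * (s1$std_error + s2$std_error))
  expect_equal(s2$intercept - s1$intercept, 0.5 * log(2), tolerance = 0.03)
})
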