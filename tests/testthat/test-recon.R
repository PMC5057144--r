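# Convolution-back-projection and phase retrieval.

test_that("an all-zero sinogram reconstructs to an all-zero volume", {
  ps <- projection_set(array(0, c(64, 1, 90)), seq(0, 178, by = 2),
                       "line_integral", beam_spec(pixel_width = 1))
  rec <- fbp_reconstruct(ps)
  expect_true(all(rec$data == 0))
})

test_that("a uniform disc reconstructs to its true attenuation", {
  n <- 128; r <- 40; mu <- 4; vw <- 2.76
  vol <- attenuation_volume(array(disc_slice(n, r, mu), c(n, n, 1)), vw)
  ps <- radon_project(vol, default_angles(720))
  rec <- fbp_reconstruct(ps, nx = n, ny = n)
  cx <- (n - 1) / 2
  inside <- outer((seq_len(n) - 1 - cx)^2, (seq_len(n) - 1 - cx)^2, `+`) <=
    (0.8 * r)^2
  expect_equal(mean(rec$data[, , 1][inside]), mu, tolerance = 0.02)
  # transmission input takes the -log route to the same result
  tr <- transmit(ps, no_noise = TRUE)
  rec2 <- fbp_reconstruct(tr, nx = n, ny = n)
  expect_equal(rec2$data, rec$data, tolerance = 1e-10)
})

test_that("reconstruction is linear", {
  n <- 96
  d1 <- disc_slice(n, 20, 3, cx = 30, cy = 40)
  d2 <- disc_slice(n, 12, 5, cx = 60, cy = 55)
  a <- default_angles(360)
  rec <- function(m) {
    v <- attenuation_volume(array(m, c(n, n, 1)), 1)
    fbp_reconstruct(radon_project(v, a), nx = n, ny = n)$data[, , 1]
  }
  r1 <- rec(d1); r2 <- rec(d2); rb <- rec(d1 + d2)
  peak <- max(abs(rb))
  expect_lt(max(abs(rb - (r1 + r2))) / peak, 1e-6)
})

test_that("insufficient angular coverage and bad kinds are refused", {
  ps <- projection_set(array(1, c(32, 1, 20)), seq(0, 95, by = 5),
                       "line_integral")
  expect_error(fbp_reconstruct(ps), class = "axotomo_coverage_error")
  prop <- projection_set(array(1, c(32, 1, 90)), seq(0, 178, by = 2),
                         "propagated_intensity")
  expect_error(fbp_reconstruct(prop), class = "axotomo_config_error")
})

test_that("forward-then-inverse recovers a phantom slice", {
  # reduced-size consistency check; the 3% bound at full problem size
  # (256^2 slice, 1,800 angles) is asserted in the acceptance suite
  p <- small_phantom(seed = 2)
  sl <- p$volume$data[, , 24]
  vol <- attenuation_volume(array(sl, c(dim(sl), 1)), p$volume$voxel_width)
  ps <- radon_project(vol, default_angles(720))
  rec <- fbp_reconstruct(ps, nx = nrow(sl), ny = ncol(sl))
  rmse <- sqrt(mean((rec$data[, , 1] - sl)^2))
  expect_lt(rmse / diff(range(sl)), 0.05)
})

test_that("phase retrieval reduces to -log at zero distance and preserves DC", {
  beam0 <- beam_spec(energy_keV = 8, pixel_width = 0.5,
                     propagation_distance_mm = 0)
  img <- array(runif(128, 0.4, 0.9), c(128, 1, 1))
  ps <- projection_set(img, 0, "transmission", beam0)
  expect_message(out <- phase_retrieve(ps), "identity")
  expect_equal(out$images, -log(img), tolerance = 1e-12)
  expect_equal(out$kind, "line_integral")

  # DC gain is exactly 1: a uniform propagated image keeps its value
  beam7 <- beam_spec(energy_keV = 8, pixel_width = 0.5,
                     propagation_distance_mm = 7, delta_beta = 400)
  unif <- projection_set(array(0.6, c(128, 1, 1)), 0, "propagated_intensity",
                         beam7)
  ret <- phase_retrieve(unif)
  expect_equal(unique(round(as.vector(ret$images), 12)), round(-log(0.6), 12))
})

test_that("phase retrieval tames the knife-edge overshoot", {
  ke <- knife_edge_set()
  pp <- fresnel_propagate(transmit(ke, no_noise = TRUE))
  raw <- -log(pp$images[, 1, 1])
  ret <- phase_retrieve(pp)$images[, 1, 1]
  ov_raw <- edge_overshoot(raw, lo = 0, hi = 1)
  ov_ret <- edge_overshoot(ret, lo = 0, hi = 1)
  expect_gt(ov_raw, 0.1)
  expect_lt(ov_ret * 5, ov_raw)
  # retrieved edge is monotone through the transition
  mid <- 256; w <- 60
  expect_true(all(diff(ret[(mid - w):(mid + w)]) >= -1e-9))
})

test_that("phase retrieval raises contrast-to-noise over absorption processing", {
  # a faint tract-like disc in 0.5 um pixels, propagated, with photon noise:
  # absorption processing buries it, retrieval recovers it
  n <- 96; vw <- 0.5
  sl <- disc_slice(n, 12, 6.5) + disc_slice(n, n, 3.9)  # tract on background
  vol <- attenuation_volume(array(sl, c(n, n, 1)), vw)
  beam <- beam_spec(energy_keV = 8, photons_per_pixel = 5e3, pixel_width = vw,
                    propagation_distance_mm = 7, delta_beta = 400)
  angles <- default_angles(240)
  ps <- radon_project(vol, angles, beam)
  noisy <- transmit(ps, beam, seed = 4)
  prop <- fresnel_propagate(noisy, beam)
  rec_abs <- fbp_reconstruct(
    projection_set(-log(pmax(prop$images, 1e-12)), angles, "line_integral",
                   beam), nx = n, ny = n)
  rec_ret <- fbp_reconstruct(phase_retrieve(prop, beam), nx = n, ny = n)
  cx <- (n - 1) / 2
  d2 <- outer((seq_len(n) - 1 - cx)^2, (seq_len(n) - 1 - cx)^2, `+`)
  tract <- d2 <= 8^2
  bg <- d2 > 20^2 & d2 <= 40^2
  cnr <- function(v) {
    s <- v$data[, , 1]
    abs(mean(s[tract]) - mean(s[bg])) / sd(s[bg])
  }
  expect_gt(cnr(rec_ret), cnr(rec_abs))
})
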