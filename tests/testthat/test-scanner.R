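# Parallel-beam forward model.

test_that("projection of a uniform disc matches chord lengths and conserves mass", {
  n <- 128; r <- 40; mu <- 4
  vw <- 2.76
  vol <- attenuation_volume(array(disc_slice(n, r, mu), c(n, n, 1)), vw)
  angles <- seq(0, 170, by = 10)
  ps <- radon_project(vol, angles)
  vox_cm <- vw * 1e-4
  ndet <- dim(ps$images)[1]
  mid <- (ndet - 1) / 2 + 1
  central <- ps$images[mid, 1, ]
  expect_equal(central, rep(2 * r * mu * vox_cm, length(angles)),
               tolerance = 5e-3)
  # mass conservation: detector sum x bin width ~ slice integral, each angle
  mass_true <- sum(vol$data[, , 1]) * vox_cm
  mass_proj <- colSums(ps$images[, 1, ])
  expect_equal(mass_proj, rep(mass_true, length(angles)), tolerance = 5e-3)
  # rotational symmetry of the centered disc
  i0 <- which(angles == 0); i90 <- which(angles == 90)
  expect_equal(ps$images[, 1, i0], ps$images[, 1, i90], tolerance = 1e-6)
})

test_that("the projector is linear", {
  n <- 64
  set.seed(3)
  v1 <- attenuation_volume(array(runif(n * n), c(n, n, 1)), 1)
  v2 <- attenuation_volume(array(runif(n * n), c(n, n, 1)), 1)
  both <- attenuation_volume(array(2 * v1$data + 3 * v2$data, c(n, n, 1)), 1)
  a <- seq(0, 175, by = 5)
  p1 <- radon_project(v1, a)$images
  p2 <- radon_project(v2, a)$images
  pb <- radon_project(both, a)$images
  expect_equal(pb, 2 * p1 + 3 * p2, tolerance = 1e-10)
  expect_error(radon_project(v1, numeric(0)), class = "axotomo_argument_error")
})

test_that("transmission follows Beer-Lambert with Poisson statistics", {
  depth <- array(1.0, c(400, 250, 1))  # 1e5 pixels of optical depth 1
  ps <- projection_set(depth, angles = 0, kind = "line_integral",
                       beam = beam_spec(photons_per_pixel = 1e4))
  clean <- transmit(ps, no_noise = TRUE)
  expect_equal(unique(as.vector(clean$images)), exp(-1))
  zero <- projection_set(array(0, c(10, 10, 1)), 0, "line_integral")
  expect_equal(unique(as.vector(transmit(zero, no_noise = TRUE)$images)), 1)
  # Poisson moments: mean transmission within 3 standard errors of exp(-1)
  noisy <- transmit(ps, seed = 5)
  m <- mean(noisy$images)
  se <- sqrt(exp(-1) / 1e4) / sqrt(length(depth))
  expect_lt(abs(m - exp(-1)), 3 * se)
  # reproducible under the seed
  noisy2 <- transmit(ps, seed = 5)
  expect_identical(noisy$images, noisy2$images)
  expect_false(identical(noisy$images, transmit(ps, seed = 6)$images))
})

test_that("free-space propagation conserves intensity and fringes a knife edge", {
  ke <- knife_edge_set()
  tr <- transmit(ke, no_noise = TRUE)
  pp <- fresnel_propagate(tr)
  expect_equal(sum(pp$images), sum(tr$images), tolerance = 1e-3)
  I <- pp$images[, 1, 1]
  # over/undershoot beyond the two plateau values
  expect_gt(edge_overshoot(I, lo = exp(-1), hi = 1), 0.05)
  # distance zero: unchanged input
  beam0 <- beam_spec(energy_keV = 8, pixel_width = 0.5,
                     propagation_distance_mm = 0)
  tr0 <- transmit(knife_edge_set(beam = beam0), no_noise = TRUE)
  expect_identical(fresnel_propagate(tr0), tr0)
  # uniform field: no structure appears
  unif <- projection_set(array(0.5, c(128, 1, 1)), 0, "transmission",
                         beam = beam_spec(energy_keV = 8, pixel_width = 0.5,
                                          propagation_distance_mm = 7))
  out <- fresnel_propagate(unif)
  expect_lt(diff(range(out$images)), 1e-9)
})
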