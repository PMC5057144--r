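# Forward model: parallel-beam line integrals of an attenuation volume,
# Beer-Lambert transmission with Poisson counting noise, and optional
# single-distance free-space propagation (projection approximation +
# Fresnel transfer function) for phase contrast.

#' Beam and detector specification
#'
#' Defaults follow a synchrotron absorption setup: monochromatic 7.13 keV
#' X-rays, 2.76 um detector pixels.  For the propagation-based configuration
#' use 8 keV, 0.5 um pixels and a 7 mm sample-detector distance.  The
#' delta/beta ratio (refractive-index decrement over absorption index) of
#' dried organic tissue is not a measured input; 400 is the package's stated
#' working assumption at 8 keV and is fully configurable.
#'
#' @param energy_keV photon energy, keV.
#' @param photons_per_pixel mean incident photons per detector pixel (I0).
#' @param pixel_width detector pixel width, um.
#' @param propagation_distance_mm sample-detector distance, mm.
#' @param delta_beta delta/beta ratio used for propagation and retrieval.
#' @return an object of class `beam_spec`.
#' @export
beam_spec <- function(energy_keV = 7.13, photons_per_pixel = 1e4,
                      pixel_width = 2.76, propagation_distance_mm = 0,
                      delta_beta = 400) {
  if (energy_keV <= 0 || photons_per_pixel <= 0 || pixel_width <= 0)
    stopf("energy, photon count and pixel width must be positive",
          class = "axotomo_domain_error")
  if (propagation_distance_mm < 0)
    stopf("propagation distance must be non-negative",
          class = "axotomo_domain_error")
  if (propagation_distance_mm > 0 && delta_beta <= 0)
    stopf("delta/beta must be positive when propagation is used",
          class = "axotomo_domain_error")
  structure(list(energy_keV = energy_keV,
                 photons_per_pixel = photons_per_pixel,
                 pixel_width = pixel_width,
                 propagation_distance_mm = propagation_distance_mm,
                 delta_beta = delta_beta),
            class = "beam_spec")
}

#' X-ray wavelength from photon energy
#'
#' `lambda[nm] = 1.2398 / E[keV]`.
#'
#' @param energy_keV photon energy in keV.
#' @return wavelength in nanometers.
#' @export
xray_wavelength_nm <- function(energy_keV) 1.2398 / energy_keV

#' Angular stack of projection images
#'
#' @param images numeric array `(detector, slice_rows, angle)`; a matrix is
#'   promoted to a single-row-of-slices stack.
#' @param angles rotation angles in degrees, strictly increasing within
#'   `[0, 360)`.
#' @param kind one of `"line_integral"`, `"transmission"`,
#'   `"propagated_intensity"`.
#' @param beam a [beam_spec()].
#' @return an object of class `projection_set`.
#' @export
projection_set <- function(images, angles, kind = c("line_integral",
                                                    "transmission",
                                                    "propagated_intensity"),
                           beam = beam_spec()) {
  kind <- match.arg(kind)
  if (is.matrix(images)) images <- array(images, c(nrow(images), 1L, ncol(images)))
  if (length(dim(images)) != 3L)
    stopf("projection images must be a 3D array (detector, rows, angle)",
          class = "axotomo_argument_error")
  if (length(angles) != dim(images)[3])
    stopf("need one image per angle (%d angles, %d images)",
          length(angles), dim(images)[3], class = "axotomo_argument_error")
  if (length(angles) == 0)
    stopf("empty angle list", class = "axotomo_argument_error")
  if (any(diff(angles) <= 0) || min(angles) < 0 || max(angles) >= 360)
    stopf("angles must be strictly increasing within [0, 360)",
          class = "axotomo_argument_error")
  if (kind == "transmission" && any(images < 0))
    stopf("transmission values must be non-negative",
          class = "axotomo_argument_error")
  structure(list(images = images, angles = as.numeric(angles), kind = kind,
                 beam = beam),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<projection_set> %s: %d detector x %d rows x %d angles (%.3g-%.3g deg)\n",
              x$kind, d[1], d[2], d[3], min(x$angles), max(x$angles)))
  invisible(x)
}

#' Default tomographic angle set
#'
#' 180 degrees covered in `n` frames (default 1,800 frames of 0.1 degrees,
#' the absorption data-collection setting; 3,000 frames of 0.06 degrees is
#' the large-field alternative).
#'
#' @param n number of frames.
#' @return angles in degrees, `[0, 180)`.
#' @export
default_angles <- function(n = 1800L) seq(0, 180, length.out = n + 1L)[seq_len(n)]

#' Parallel-beam forward projection
#'
#' Computes line integrals of the attenuation volume (optical depth,
#' dimensionless; lengths in cm so a 1 cm path through 1 cm^-1 material has
#' depth 1).  The rotation axis is z: each z-slice is projected
#' independently onto a 1D detector row.  Ray integration is rotate-and-sum
#' with bilinear interpolation at 0.5-pixel steps.
#'
#' @param volume an [attenuation_volume()].
#' @param angles projection angles in degrees.
#' @param beam a [beam_spec()]; its pixel width is set to the volume voxel
#'   width (detector at unit magnification).
#' @param ndet number of detector bins (default: wide enough for the slice
#'   diagonal).
#' @return a [projection_set()] of kind `line_integral`.
#' @export
radon_project <- function(volume, angles = default_angles(), beam = NULL,
                          ndet = NULL) {
  stopifnot(inherits(volume, "attenuation_volume"))
  if (length(angles) == 0)
    stopf("empty angle list", class = "axotomo_argument_error")
  d <- dim(volume$data)
  ndet <- ndet %||% (ceiling(sqrt(d[1]^2 + d[2]^2)) + 2L)
  beam <- beam %||% beam_spec(pixel_width = volume$voxel_width)
  beam$pixel_width <- volume$voxel_width
  vox_cm <- volume$voxel_width * 1e-4
  arad <- angles * pi / 180
  out <- array(0, c(ndet, d[3], length(angles)))
  for (k in seq_len(d[3])) {
    sino <- radon_forward_cpp(volume$data[, , k], arad, as.integer(ndet),
                              0.5, 0)
    out[, k, ] <- sino * vox_cm
  }
  projection_set(out, angles, "line_integral", beam)
}

#' Beer-Lambert transmission with Poisson photon noise
#'
#' Expected counts are `I0 * exp(-depth)`; measured counts are Poisson
#' samples, flat-field normalized by `I0`.  With `no_noise = TRUE` the
#' infinite-flux limit `exp(-depth)` is returned.
#'
#' @param projections a [projection_set()] of kind `line_integral`.
#' @param beam a [beam_spec()] providing `photons_per_pixel`; defaults to
#'   the set's own beam.
#' @param seed RNG seed for the noise realization.
#' @param no_noise skip Poisson sampling.
#' @return a [projection_set()] of kind `transmission`.
#' @export
transmit <- function(projections, beam = NULL, seed = 1L, no_noise = FALSE) {
  stopifnot(inherits(projections, "projection_set"))
  if (projections$kind != "line_integral")
    stopf("transmit() needs line-integral projections, got '%s'",
          projections$kind, class = "axotomo_argument_error")
  beam <- beam %||% projections$beam
  I0 <- beam$photons_per_pixel
  if (is.null(I0) || I0 <= 0)
    stopf("photons_per_pixel must be positive", class = "axotomo_argument_error")
  expected <- exp(-projections$images)
  if (no_noise) {
    imgs <- expected
  } else {
    counts <- with_seed(seed, rpois(length(expected), I0 * expected))
    imgs <- array(counts / I0, dim(expected))
  }
  projection_set(imgs, projections$angles, "transmission", beam)
}

# pad a matrix by edge replication to target dims
pad_replicate <- function(m, nr, nc) {
  out <- matrix(0, nr, nc)
  r0 <- floor((nr - nrow(m)) / 2); c0 <- floor((nc - ncol(m)) / 2)
  ri <- pmin(pmax(seq_len(nr) - r0, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(nc) - c0, 1L), ncol(m))
  out[] <- m[ri, ci]
  attr(out, "crop") <- c(r0 + 1L, r0 + nrow(m), c0 + 1L, c0 + ncol(m))
  out
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# fft frequencies in cycles per unit, for n samples of spacing `d`
fft_freq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

#' Free-space propagation of transmission images
#'
#' Builds a projection-approximation wavefield from the optical depth
#' (amplitude `exp(-d/2)`, phase `(delta/beta) * d / 2`), propagates it by
#' the Fresnel transfer function `exp(-i pi lambda z f^2)` over the
#' sample-detector distance, and returns the detected intensity.  The
#' transfer function is unimodular, so total intensity is conserved.
#'
#' @param projections a [projection_set()] of kind `transmission`.
#' @param beam a [beam_spec()] with a positive `propagation_distance_mm`;
#'   defaults to the set's own beam.  Distance 0 returns the input
#'   unchanged.
#' @return a [projection_set()] of kind `propagated_intensity`.
#' @export
fresnel_propagate <- function(projections, beam = NULL) {
  stopifnot(inherits(projections, "projection_set"))
  if (projections$kind != "transmission")
    stopf("fresnel_propagate() needs transmission projections, got '%s'",
          projections$kind, class = "axotomo_argument_error")
  beam <- beam %||% projections$beam
  z_um <- beam$propagation_distance_mm * 1000
  if (z_um == 0) return(projections)
  lambda_um <- xray_wavelength_nm(beam$energy_keV) * 1e-3
  px <- beam$pixel_width
  db <- beam$delta_beta
  d <- dim(projections$images)
  out <- array(0, d)
  nr <- next_pow2(max(d[1] + 32, 2 * d[1]))
  nc <- if (d[2] == 1) 1L else next_pow2(max(d[2] + 32, 2 * d[2]))
  fr <- fft_freq(nr, px)
  fc <- if (nc == 1L) 0 else fft_freq(nc, px)
  f2 <- outer(fr^2, fc^2, `+`)
  H <- exp(-1i * pi * lambda_um * z_um * f2)
  for (a in seq_len(d[3])) {
    tr <- pmax(matrix(projections$images[, , a], d[1], d[2]), 1e-12)
    depth <- -log(tr)
    U0 <- matrix(exp(complex(real = -depth / 2, imaginary = db * depth / 2)),
                 d[1], d[2])
    Pre <- pad_replicate(Re(U0), nr, nc)
    crop <- attr(Pre, "crop")
    P <- Pre + 1i * pad_replicate(Im(U0), nr, nc)
    Uz <- fft(fft(P) * H, inverse = TRUE) / length(P)
    I <- Mod(Uz)^2
    out[, , a] <- I[crop[1]:crop[2], crop[3]:crop[4]]
  }
  projection_set(out, projections$angles, "propagated_intensity", beam)
}
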