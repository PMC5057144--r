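# Inverse model: convolution-back-projection (filtered back-projection)
# slice reconstruction and single-material single-distance phase retrieval.

#' Reconstruction configuration
#'
#' @param filter_kind `"ramp"` (Ram-Lak, default) or `"cosine"`
#'   (cosine-apodized ramp).
#' @param circle_mask zero voxels outside the inscribed circle of each
#'   slice.
#' @param rotation_center rotation center on the detector axis, in pixels
#'   (may be fractional); default is the detector midline.
#' @param ring_correction apply a sinogram median-detrend before filtering
#'   (off by default; ring artefacts are part of the plain reconstruction).
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(filter_kind = c("ramp", "cosine"),
                         circle_mask = FALSE, rotation_center = NULL,
                         ring_correction = FALSE) {
  filter_kind <- match.arg(filter_kind)
  structure(list(filter_kind = filter_kind, circle_mask = isTRUE(circle_mask),
                 rotation_center = rotation_center,
                 ring_correction = isTRUE(ring_correction)),
            class = "recon_config")
}

# Frequency response of the band-limited ramp (Ram-Lak) kernel of length n
# (n a power of two >= 2 * ndet), detector spacing 1: spatial kernel
# h(0) = 1/4, h(odd) = -1/(pi n)^2, h(even) = 0, Fourier-transformed.
ramp_response <- function(n, kind = "ramp") {
  offs <- c(0:(n / 2), (-n / 2 + 1):-1)
  h <- numeric(n)
  h[1] <- 0.25
  odd <- which(offs %% 2 != 0)
  h[odd] <- -1 / (pi * offs[odd])^2
  H <- Re(fft(h))
  if (kind == "cosine") {
    f <- fft_freq(n)            # cycles/sample, Nyquist 0.5
    H <- H * cos(pi * f)        # cosine apodization, zero at Nyquist
  }
  H
}

# Filter a sinogram (ndet x nangle) with the ramp response; returns same size.
filter_sinogram <- function(sino, kind = "ramp") {
  ndet <- nrow(sino)
  n <- next_pow2(2 * ndet)
  H <- ramp_response(n, kind)
  p <- rbind(sino, matrix(0, n - ndet, ncol(sino)))
  q <- Re(mvfft(mvfft(p) * H, inverse = TRUE)) / n
  q[seq_len(ndet), , drop = FALSE]
}

#' Filtered back-projection reconstruction
#'
#' Slice-by-slice convolution-back-projection perpendicular to the rotation
#' axis.  Line-integral projections are used directly; transmission
#' projections are `-log`-converted first (non-positive values are clipped
#' to the smallest positive representable value and counted in the
#' `clipped_pixels` QC attribute).  Output voxel values are scaled to cm^-1
#' using the detector pixel width.
#'
#' @param projections a [projection_set()] of kind `line_integral` or
#'   `transmission` (propagated intensity must go through
#'   [phase_retrieve()] first).
#' @param cfg a [recon_config()].
#' @param nx,ny output slice dimensions (default: square of the detector
#'   width rounded to the enclosing volume, `ndet` is used for both).
#' @return an [attenuation_volume()].
#' @export
fbp_reconstruct <- function(projections, cfg = recon_config(), nx = NULL,
                            ny = NULL) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(cfg, "recon_config"))
  if (projections$kind == "propagated_intensity")
    stopf("propagated intensity must be phase-retrieved before reconstruction",
          class = "axotomo_config_error")
  coverage <- max(projections$angles) - min(projections$angles)
  na <- length(projections$angles)
  if (coverage + (coverage / max(na - 1, 1)) < 160)
    stopf("angular coverage %.1f deg is below the 160 deg minimum",
          coverage, class = "axotomo_coverage_error")
  d <- dim(projections$images)
  ndet <- d[1]
  nx <- nx %||% ndet
  ny <- ny %||% ndet
  center_offset <- if (is.null(cfg$rotation_center)) 0 else
    cfg$rotation_center - (ndet - 1) / 2
  if (!is.null(cfg$rotation_center) &&
      (cfg$rotation_center < 0 || cfg$rotation_center > ndet - 1))
    stopf("rotation center %.1f outside detector width", cfg$rotation_center,
          class = "axotomo_config_error")
  px_cm <- projections$beam$pixel_width * 1e-4
  arad <- projections$angles * pi / 180
  clipped <- 0L
  vol <- array(0, c(nx, ny, d[2]))
  for (k in seq_len(d[2])) {
    sino <- matrix(projections$images[, k, ], ndet, na)
    if (projections$kind == "transmission") {
      bad <- sino <= 0
      clipped <- clipped + sum(bad)
      sino[bad] <- .Machine$double.xmin
      sino <- -log(sino)
    }
    if (cfg$ring_correction) {
      prof <- apply(sino, 1, stats::median)
      sino <- sino - (prof - stats::median(prof))
    }
    q <- filter_sinogram(sino, cfg$filter_kind)
    rec <- backproject_cpp(q, arad, as.integer(nx), as.integer(ny),
                           center_offset) * pi / na
    vol[, , k] <- rec / px_cm
  }
  if (clipped > 0)
    message(sprintf("fbp_reconstruct: clipped %d non-positive transmission pixels",
                    clipped))
  if (cfg$circle_mask) {
    cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
    r2 <- (min(nx, ny) / 2)^2
    m <- outer((seq_len(nx) - 1 - cx)^2, (seq_len(ny) - 1 - cy)^2, `+`) > r2
    for (k in seq_len(d[2])) { s <- vol[, , k]; s[m] <- 0; vol[, , k] <- s }
  }
  out <- attenuation_volume(vol, voxel_width = projections$beam$pixel_width)
  out$qc <- list(clipped_pixels = clipped)
  add_provenance(out, "fbp_reconstruct",
                 parameters = list(filter = cfg$filter_kind, n_angles = na))
}

#' Single-material single-distance phase retrieval
#'
#' Applies the low-pass transfer filter `1 / (1 + C |k|^2)` with
#' `C = z * (delta/beta) * lambda / (4 pi)` (k the angular spatial
#' frequency) to each propagated-intensity image, then takes `-log`,
#' returning retrieved optical depth.  The filter has unit gain at DC, so
#' mean projection values are preserved before the log.  With a zero
#' propagation distance the filter degenerates to the identity and the
#' result is the plain `-log` of the input (a message notes this).
#'
#' @param projections a [projection_set()] of kind `propagated_intensity`
#'   (or `transmission`, for the zero-distance degenerate case).
#' @param beam a [beam_spec()]; defaults to the set's own beam.
#' @return a [projection_set()] of kind `line_integral`.
#' @export
phase_retrieve <- function(projections, beam = NULL) {
  stopifnot(inherits(projections, "projection_set"))
  if (!projections$kind %in% c("propagated_intensity", "transmission"))
    stopf("phase_retrieve() expects intensity images, got '%s'",
          projections$kind, class = "axotomo_argument_error")
  beam <- beam %||% projections$beam
  z_um <- beam$propagation_distance_mm * 1000
  lambda_um <- xray_wavelength_nm(beam$energy_keV) * 1e-3
  C <- z_um * beam$delta_beta * lambda_um / (4 * pi)  # um^2, for k in rad/um
  d <- dim(projections$images)
  out <- array(0, d)
  if (C == 0) {
    message("phase_retrieve: zero propagation distance, identity filter (-log only)")
    out[] <- -log(pmax(projections$images, .Machine$double.xmin))
    return(projection_set(out, projections$angles, "line_integral", beam))
  }
  px <- beam$pixel_width
  nr <- next_pow2(max(d[1] + 32, 2 * d[1]))
  nc <- if (d[2] == 1) 1L else next_pow2(max(d[2] + 32, 2 * d[2]))
  kr <- 2 * pi * fft_freq(nr, px)
  kc <- if (nc == 1L) 0 else 2 * pi * fft_freq(nc, px)
  k2 <- outer(kr^2, kc^2, `+`)
  G <- 1 / (1 + C * k2)
  for (a in seq_len(d[3])) {
    img <- matrix(projections$images[, , a, drop = TRUE], d[1], d[2])
    P <- pad_replicate(img, nr, nc)
    crop <- attr(P, "crop")
    flt <- Re(fft(fft(P) * G, inverse = TRUE)) / length(P)
    flt <- flt[crop[1]:crop[2], crop[3]:crop[4]]
    out[, , a] <- -log(pmax(flt, .Machine$double.xmin))
  }
  projection_set(out, projections$angles, "line_integral", beam)
}
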