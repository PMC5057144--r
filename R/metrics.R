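# Quantitative analyses of reconstructed volumes: attenuation histograms in
# 0.1 cm^-1 bins, Fourier-domain spatial-resolution estimation, and the
# SNR-vs-voxel-width scaling law.

# coerce volume/slice input to (values, pixel width)
as_image_values <- function(x) {
  if (inherits(x, "attenuation_volume"))
    list(values = x$data, pixel_width = x$voxel_width)
  else if (is.numeric(x))
    list(values = x, pixel_width = attr(x, "pixel_width") %||% 1)
  else stopf("expected an attenuation_volume or numeric array",
             class = "axotomo_argument_error")
}

#' Attenuation histogram over a region of interest
#'
#' Counts pixels per attenuation bin.  Bins are `bin_width` cm^-1 wide
#' (default 0.1) and aligned so that a bin edge falls at 0.0 cm^-1.  The
#' summary also reports the mode bin center and the contiguous peak range:
#' the run of bins around the mode whose counts stay at or above
#' `peak_frac` times the mode count (the "broad peak from a to b" style
#' statement).
#'
#' @param x an [attenuation_volume()], or a numeric matrix/array of
#'   attenuation values.
#' @param roi optional region of interest in micrometers: a 2-column matrix
#'   with one row per dimension giving `(min, max)` map coordinates (e.g. a
#'   360 x 360 um box of a slice).  `NULL` uses everything.
#' @param bin_width bin width in cm^-1.
#' @param peak_frac fraction of the mode count defining the peak range.
#' @return an object of class `attenuation_histogram`; its `bins` element
#'   is a tibble with `bin_lo`, `bin_hi`, `mid`, `count`.
#' @export
attenuation_histogram <- function(x, roi = NULL, bin_width = 0.1,
                                  peak_frac = 0.1) {
  if (bin_width <= 0)
    stopf("bin width must be positive", class = "axotomo_argument_error")
  im <- as_image_values(x)
  v <- im$values
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    dv <- dim(v) %||% length(v)
    if (nrow(roi) > length(dv))
      stopf("ROI has more dimensions than the image",
            class = "axotomo_argument_error")
    idx <- vector("list", length(dv))
    for (d in seq_along(dv)) {
      if (d <= nrow(roi)) {
        lo <- ceiling(um_to_index(roi[d, 1], im$pixel_width))
        hi <- floor(um_to_index(roi[d, 2], im$pixel_width))
        if (lo < 1 || hi > dv[d] || lo > hi)
          stopf("ROI dimension %d ([%g, %g] um) outside image bounds", d,
                roi[d, 1], roi[d, 2], class = "axotomo_argument_error")
        idx[[d]] <- lo:hi
      } else idx[[d]] <- seq_len(dv[d])
    }
    v <- do.call(`[`, c(list(v), idx))
  }
  v <- as.numeric(v)
  lo_edge <- bin_width * floor(min(v) / bin_width)
  hi_edge <- bin_width * (floor(max(v) / bin_width) + 1)
  edges <- seq(lo_edge, hi_edge, by = bin_width)
  counts <- tabulate(pmin(floor((v - lo_edge) / bin_width) + 1L,
                          length(edges) - 1L),
                     nbins = length(edges) - 1L)
  bins <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                         mid = (edges[-length(edges)] + edges[-1]) / 2,
                         count = counts)
  imode <- which.max(counts)
  thr <- peak_frac * counts[imode]
  lo_i <- imode; while (lo_i > 1 && counts[lo_i - 1] >= thr) lo_i <- lo_i - 1
  hi_i <- imode; while (hi_i < length(counts) && counts[hi_i + 1] >= thr)
    hi_i <- hi_i + 1
  structure(list(bins = bins, bin_width = bin_width, roi = roi,
                 n_pixels = length(v), mode_center = bins$mid[imode],
                 peak_range = c(bins$bin_lo[lo_i], bins$bin_hi[hi_i]),
                 peak_frac = peak_frac),
            class = "attenuation_histogram")
}

#' @export
print.attenuation_histogram <- function(x, ...) {
  cat(sprintf(paste0("<attenuation_histogram> %d pixels in %.2g cm^-1 bins; ",
                     "mode %.2f cm^-1, peak %.1f-%.1f cm^-1\n"),
              x$n_pixels, x$bin_width, x$mode_center, x$peak_range[1],
              x$peak_range[2]))
  invisible(x)
}

#' @rdname attenuation_histogram
#' @param object an `attenuation_histogram`.
#' @param ... ignored.
#' @export
autoplot.attenuation_histogram <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression("linear attenuation coefficient (cm"^-1 * ")"),
                  y = "pixels per bin") +
    ggplot2::theme_minimal()
}

# ---- Fourier-domain resolution --------------------------------------------

#' Spatial resolution from a Fourier-domain plot
#'
#' Estimates the spatial resolution of a 2D image from its azimuthally
#' averaged power spectrum.  The image is Hann-windowed, transformed, and
#' the log power is averaged in radial frequency bins; a straight signal
#' line in log-power vs squared-frequency coordinates (the signature of a
#' Gaussian-like system MTF) is fit where the spectrum stands above a flat
#' noise floor estimated from the highest frequencies.  The resolution is
#' the inverse of the frequency where the fitted signal line crosses the
#' noise floor.  If no signal decay is detected (e.g. pure noise) the
#' estimate fails with status `"no_signal"` rather than returning a number.
#'
#' @param image 2D numeric matrix (at least 64 x 64), or a single-slice
#'   [attenuation_volume()].
#' @param pixel_width pixel width in micrometers (taken from the volume if
#'   one is given).
#' @param n_bins number of radial frequency bins (>= 64 recommended).
#' @return an object of class `resolution_estimate` with fields
#'   `resolution` (um; `NA` on failure), `status` (`"ok"`,
#'   `"nyquist_limited"` or `"no_signal"`), `method`, and `fit` (intercept,
#'   slope, noise floor, crossing frequency).
#' @export
estimate_resolution_fourier <- function(image, pixel_width = NULL,
                                        n_bins = 64L) {
  if (inherits(image, "attenuation_volume")) {
    pixel_width <- pixel_width %||% image$voxel_width
    image <- image$data[, , 1]
  }
  pixel_width <- pixel_width %||% 1
  if (!is.matrix(image) || min(dim(image)) < 64)
    stopf("resolution estimation needs a 2D image of side >= 64",
          class = "axotomo_argument_error")
  nr <- nrow(image); nc <- ncol(image)
  wr <- 0.5 * (1 - cos(2 * pi * seq(0, nr - 1) / (nr - 1)))
  wc <- 0.5 * (1 - cos(2 * pi * seq(0, nc - 1) / (nc - 1)))
  w <- outer(wr, wc)
  centered <- (image - mean(image)) * w
  P <- Mod(fft(centered))^2 / length(centered)
  fr <- fft_freq(nr, pixel_width)
  fc <- fft_freq(nc, pixel_width)
  fmag <- sqrt(outer(fr^2, fc^2, `+`))
  f_nyq <- 0.5 / pixel_width
  sel <- fmag > 0 & fmag <= f_nyq
  bins <- pmin(ceiling(fmag[sel] / f_nyq * n_bins), n_bins)
  logp <- tapply(log(P[sel] + .Machine$double.xmin), bins, mean)
  fb <- (as.numeric(names(logp)) - 0.5) / n_bins * f_nyq
  # noise floor from the top 20% of the frequency range
  floor_sel <- fb > 0.8 * f_nyq
  if (sum(floor_sel) < 3) floor_sel <- fb > 0.7 * f_nyq
  noise_floor <- stats::median(logp[floor_sel])
  sig_sel <- logp > noise_floor + 1 & fb <= 0.8 * f_nyq
  fail <- function(status) structure(
    list(resolution = NA_real_, status = status,
         method = "azimuthal log-power vs f^2 crossing",
         fit = list(intercept = NA, slope = NA, noise_floor = noise_floor,
                    crossing_freq = NA),
         spectrum = tibble::tibble(freq = fb, log_power = as.numeric(logp)),
         pixel_width = pixel_width),
    class = "resolution_estimate")
  if (sum(sig_sel) < 5) return(fail("no_signal"))
  fit <- lm(y ~ x, data = data.frame(x = fb[sig_sel]^2, y = logp[sig_sel]))
  a <- coef(fit)[1]; b <- coef(fit)[2]
  if (b >= 0) return(fail("no_signal"))
  kc2 <- (noise_floor - a) / b
  if (kc2 <= 0) return(fail("no_signal"))
  kc <- sqrt(kc2)
  status <- "ok"
  if (kc > f_nyq) { kc <- f_nyq; status <- "nyquist_limited" }
  res <- max(1 / kc, 2 * pixel_width)
  structure(list(resolution = res, status = status,
                 method = "azimuthal log-power vs f^2 crossing",
                 fit = list(intercept = unname(a), slope = unname(b),
                            noise_floor = noise_floor, crossing_freq = kc),
                 spectrum = tibble::tibble(freq = fb,
                                           log_power = as.numeric(logp)),
                 pixel_width = pixel_width),
            class = "resolution_estimate")
}

#' @export
print.resolution_estimate <- function(x, ...) {
  if (is.na(x$resolution))
    cat(sprintf("<resolution_estimate> failed: %s\n", x$status))
  else
    cat(sprintf("<resolution_estimate> %.2f um (%s; crossing %.3g cycles/um)\n",
                x$resolution, x$status, x$fit$crossing_freq))
  invisible(x)
}

# ---- SNR vs voxel width ----------------------------------------------------

#' SNR scaling with voxel width
#'
#' Photons collected per voxel grow with the voxel volume (width cubed)
#' while the SNR of a counting measurement grows with the square root of
#' the count, so the reconstructed-region SNR is expected to scale as the
#' 3/2 power of the voxel width.  This operation simulates Poisson counts
#' with mean `photons_per_um3 * width^3` over a uniform region for each
#' width, computes SNR = mean / standard deviation, and fits the log-log
#' slope by least squares.
#'
#' @param widths voxel widths in micrometers (at least 3).
#' @param photons_per_um3 mean photons per cubic micrometer.
#' @param n_samples voxels sampled per width.
#' @param seed RNG seed.
#' @param no_noise refused: a zero-variance sample has no SNR; present so
#'   callers hitting the degenerate path get a clear error.
#' @return an object of class `snr_scaling`: tibble `measurements`
#'   (width, mean, sd, snr), `exponent`, `std_error`, `intercept`.
#' @examples
#' s <- snr_scaling(c(1, 2, 4, 8), n_samples = 1e4, seed = 1)
#' s$exponent
#' @export
snr_scaling <- function(widths, photons_per_um3 = 20, n_samples = 1e5,
                        seed = 1L, no_noise = FALSE) {
  if (length(widths) < 3)
    stopf("need at least 3 voxel widths", class = "axotomo_argument_error")
  if (isTRUE(no_noise))
    stopf("SNR is undefined for a zero-variance (noise-free) simulation",
          class = "axotomo_degenerate_error")
  meas <- with_seed(seed, {
    do.call(rbind, lapply(widths, function(w) {
      counts <- rpois(n_samples, photons_per_um3 * w^3)
      s <- sd(counts)
      if (s == 0)
        stopf("degenerate sample at width %g um (zero variance)", w,
              class = "axotomo_degenerate_error")
      data.frame(width = w, mean = mean(counts), sd = s,
                 snr = mean(counts) / s)
    }))
  })
  fit <- lm(log(snr) ~ log(width), data = meas)
  sm <- summary(fit)$coefficients
  structure(list(measurements = tibble::as_tibble(meas),
                 exponent = unname(coef(fit)[2]),
                 std_error = unname(sm["log(width)", "Std. Error"]),
                 intercept = unname(coef(fit)[1]),
                 photons_per_um3 = photons_per_um3,
                 n_samples = n_samples),
            class = "snr_scaling")
}

#' @export
print.snr_scaling <- function(x, ...) {
  cat(sprintf("<snr_scaling> fitted exponent %.3f +/- %.3f over widths {%s} um\n",
              x$exponent, x$std_error,
              paste(x$measurements$width, collapse = ", ")))
  invisible(x)
}

#' @rdname snr_scaling
#' @param object an `snr_scaling` result.
#' @param ... ignored.
#' @export
autoplot.snr_scaling <- function(object, ...) {
  ggplot2::ggplot(object$measurements,
                  ggplot2::aes(x = .data$width, y = .data$snr)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(stat = "smooth", method = "lm", formula = y ~ x,
                       linetype = 2, alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "voxel width (um)", y = "SNR") +
    ggplot2::theme_minimal()
}
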