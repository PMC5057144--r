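# Volume and projection I/O: multi-page TIFF slice stacks with a YAML
# metadata sidecar (voxel width, units, scale/offset, provenance).  Sidecars
# are plain text because TIFF tag dialects are fragile across tools.
#
# Attenuation values are stored as 32-bit samples spanning an affine range
# recorded in the sidecar (value = scale * stored + offset, stored in
# [0, 1]).  The 2^32-level quantization resolves the stored range about two
# orders of magnitude finer than IEEE single precision, so volumes
# round-trip exactly at 32-bit float precision.

sidecar_path <- function(path) paste0(path, ".meta.yaml")

write_scaled_stack <- function(pages, path) {
  lo <- min(vapply(pages, min, 0))
  hi <- max(vapply(pages, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(pages, function(p) (p - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  list(scale = scale, offset = lo)
}

#' Write an attenuation volume as a TIFF slice stack
#'
#' Slices perpendicular to the rotation (z) axis become pages of a
#' multi-page 32-bit TIFF; metadata (voxel width, units, shape, the
#' value-range scale/offset, provenance) goes to a `<path>.meta.yaml`
#' sidecar.
#'
#' @param volume an [attenuation_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "attenuation_volume"))
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[3]), function(k) volume$data[, , k])
  sc <- write_scaled_stack(pages, path)
  meta <- list(kind = "attenuation_volume", voxel_width_um = volume$voxel_width,
               units = volume$units, shape = as.integer(d),
               sample_format = "unit_scaled", scale = sc$scale,
               offset = sc$offset, provenance = volume$provenance)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

read_stack_pages <- function(path, as_is) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = as_is),
                    error = function(e)
                      stopf("failed to read TIFF stack '%s': %s", path,
                            conditionMessage(e), class = "axotomo_io_error"))
  if (!is.list(pages)) pages <- list(pages)
  # grayscale pages may come back with a trailing channel dimension
  lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
}

#' Read an attenuation volume from a TIFF slice stack
#'
#' Stacks written by [write_volume()] restore exactly (beyond single-float
#' precision) via the sidecar's scale/offset.  8/16-bit integer stacks from
#' other tools are mapped to cm^-1 as `value = scale * raw + offset` using
#' the sidecar's fields (`sample_format: uint`).  A missing sidecar falls
#' back to defaults (voxel width 1 um) with a warning.
#'
#' @param path TIFF path.
#' @return an [attenuation_volume()].
#' @export
read_volume <- function(path) {
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- yaml::read_yaml(sidecar_path(path))
  } else {
    warning(sprintf("no metadata sidecar for '%s'; assuming voxel width 1 um",
                    path))
  }
  fmt <- meta$sample_format %||% "unit_scaled"
  pages <- read_stack_pages(path, as_is = fmt %in% c("uint", "int"))
  shape <- unlist(meta$shape) %||% c(dim(pages[[1]]), length(pages))
  if (length(pages) != shape[3])
    stopf("TIFF stack '%s' has %d pages but sidecar declares %d (page %d missing or truncated)",
          path, length(pages), shape[3], min(length(pages), shape[3]) + 1L,
          class = "axotomo_io_error")
  for (k in seq_along(pages)) {
    if (!all(dim(pages[[k]]) == shape[1:2]))
      stopf("page %d of '%s' has dimensions %s, expected %d x %d",
            k, path, paste(dim(pages[[k]]), collapse = " x "),
            shape[1], shape[2], class = "axotomo_io_error")
  }
  arr <- array(0, shape)
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  scale <- meta$scale %||% 1
  offset <- meta$offset %||% 0
  arr <- scale * arr + offset
  attenuation_volume(arr, voxel_width = meta$voxel_width_um %||% 1,
                     provenance = meta$provenance %||% list())
}

#' Write a projection set as a TIFF stack
#'
#' One page per rotation angle; angles, kind, value scale/offset and beam
#' geometry go to the sidecar.
#'
#' @param projections a [projection_set()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_projections <- function(projections, path) {
  stopifnot(inherits(projections, "projection_set"))
  na <- dim(projections$images)[3]
  pages <- lapply(seq_len(na), function(a)
    matrix(projections$images[, , a], dim(projections$images)[1]))
  sc <- write_scaled_stack(pages, path)
  meta <- list(kind = "projection_set", projection_kind = projections$kind,
               angles_deg = projections$angles,
               shape = as.integer(dim(projections$images)),
               sample_format = "unit_scaled", scale = sc$scale,
               offset = sc$offset, beam = unclass(projections$beam))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a projection set written by [write_projections()]
#'
#' @param path TIFF path.
#' @return a [projection_set()].
#' @export
read_projections <- function(path) {
  if (!file.exists(sidecar_path(path)))
    stopf("projection stacks need their metadata sidecar ('%s' missing)",
          sidecar_path(path), class = "axotomo_io_error")
  meta <- yaml::read_yaml(sidecar_path(path))
  if (!identical(meta$kind, "projection_set"))
    stopf("'%s' is not a projection-set stack", path, class = "axotomo_io_error")
  pages <- read_stack_pages(path, as_is = FALSE)
  shape <- unlist(meta$shape)
  if (length(pages) != shape[3])
    stopf("projection stack '%s' has %d pages, sidecar declares %d",
          path, length(pages), shape[3], class = "axotomo_io_error")
  arr <- array(0, shape)
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr <- (meta$scale %||% 1) * arr + (meta$offset %||% 0)
  beam <- do.call(beam_spec, meta$beam)
  projection_set(arr, angles = unlist(meta$angles_deg),
                 kind = meta$projection_kind, beam = beam)
}
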