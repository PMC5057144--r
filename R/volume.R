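# AttenuationVolume: the central image object, a 3D grid of linear
# attenuation coefficients (cm^-1) with a voxel width in micrometers.
# Voxel (i, j, k) has its center at ((i-1), (j-1), (k-1)) * voxel_width in
# micrometer map coordinates; the map origin is the center of voxel (1,1,1).

#' Construct an attenuation volume
#'
#' @param data numeric 3D array (or a matrix, promoted to a single-slice
#'   volume) of linear attenuation coefficients in cm^-1.
#' @param voxel_width voxel edge length in micrometers.
#' @param provenance optional list of provenance records.
#' @return an object of class `attenuation_volume`.
#' @examples
#' v <- attenuation_volume(array(3.9, c(8, 8, 4)), voxel_width = 2.76)
#' v
#' @export
attenuation_volume <- function(data, voxel_width, provenance = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("volume data must be a 3D array", class = "axotomo_domain_error")
  if (!is.numeric(voxel_width) || voxel_width <= 0)
    stopf("voxel width must be positive", class = "axotomo_domain_error")
  structure(list(data = data, voxel_width = as.numeric(voxel_width),
                 units = "cm^-1", provenance = provenance),
            class = "attenuation_volume")
}

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<attenuation_volume> %d x %d x %d voxels @ %.3g um ",
                     "(%.3g x %.3g x %.3g mm), range [%.3g, %.3g] cm^-1\n"),
              d[1], d[2], d[3], x$voxel_width,
              d[1] * x$voxel_width / 1000, d[2] * x$voxel_width / 1000,
              d[3] * x$voxel_width / 1000,
              min(x$data), max(x$data)))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "operation"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.attenuation_volume <- function(x) dim(x$data)

# append a provenance record
add_provenance <- function(vol, operation, parameters = list(), seed = NULL) {
  vol$provenance <- c(vol$provenance,
                      list(list(operation = operation, parameters = parameters,
                                seed = seed,
                                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))))
  vol
}

# index <-> micrometer coordinate conversion (voxel centers)
index_to_um <- function(idx, voxel_width) (idx - 1) * voxel_width
um_to_index <- function(um, voxel_width) um / voxel_width + 1

#' Select voxels inside a rendering range
#'
#' The attenuation-range selection used when volume-rendering a structure of
#' interest (e.g. rendering 1.6 to 3.4 cm^-1 to isolate a tract system).
#'
#' @param volume an [attenuation_volume()].
#' @param lo,hi inclusive range bounds in cm^-1, `lo < hi`.
#' @return a logical array of the same shape, `TRUE` where
#'   `lo <= mu <= hi`.
#' @export
render_range_mask <- function(volume, lo, hi) {
  stopifnot(inherits(volume, "attenuation_volume"))
  if (!(lo < hi))
    stopf("rendering range needs lo < hi (got [%g, %g])", lo, hi,
          class = "axotomo_argument_error")
  volume$data >= lo & volume$data <= hi
}
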