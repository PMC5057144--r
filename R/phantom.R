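# Seeded synthetic phantoms of freeze-dried striatum-like tissue.
#
# A phantom is a 3D attenuation volume holding: a uniform dried-tissue
# background; smooth tube-like axonal tracts of elevated attenuation fanning
# from the +x face (the basal surface of the cerebral cortex) to scattered
# interior endpoints; low-density spherical nuclei a few micrometers in
# diameter; and optionally a vessel near the bottom of the field.  The
# generator also returns the exact tract centerlines as a wire model plus a
# per-voxel label volume, which downstream tracing results are scored
# against.

NUCLEUS_LABEL <- -1L
VESSEL_LABEL <- -2L

#' Specification of a synthetic tissue phantom
#'
#' Defaults emulate the model-building conditions of a freeze-dried mouse
#' striatum dataset: 2.76 um voxels, a 400 x 400 x 167 voxel field
#' (about 1.1 x 1.1 x 0.46 mm^3), a background near the dried whole-brain
#' prediction of 3.9 cm^-1, tracts in the upper part of the observed
#' 2.5-8.0 cm^-1 attenuation peak, and nuclei several micrometers across
#' with attenuation below background.  Tract radii are an assumption (the
#' source imagery does not resolve individual axons): 5-9 um, i.e. tract
#' diameters of 10-18 um.
#'
#' @param shape volume dimensions in voxels, length-3 integer.
#' @param voxel_width voxel edge length, um.
#' @param n_tracts number of axonal tracts.
#' @param tract_radius_range tract tube radius range, um.
#' @param background_mu background attenuation, cm^-1.
#' @param tract_mu tract attenuation, cm^-1.
#' @param nucleus_mu nucleus attenuation, cm^-1 (below background).
#' @param n_nuclei number of spherical nuclei.
#' @param nucleus_diameter_range nucleus diameter range, um.
#' @param include_vessel add a vessel-like tube near the bottom face.
#' @param vessel_mu vessel attenuation, cm^-1; the default is below
#'   background because the lumen empties and fills with air on drying.
#' @param bifurcations allow a fraction of tracts to carry a side branch
#'   that rejoins the fan geometry; off by default so tract counts remain
#'   unambiguous.
#' @param seed RNG seed; the phantom is bit-reproducible given the seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(400L, 400L, 167L), voxel_width = 2.76,
                         n_tracts = 20L, tract_radius_range = c(5, 9),
                         background_mu = 3.9, tract_mu = 6.5,
                         nucleus_mu = 1.5, n_nuclei = 150L,
                         nucleus_diameter_range = c(4, 8),
                         include_vessel = TRUE, vessel_mu = 1.0,
                         bifurcations = FALSE, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stopf("phantom shape must be 3 dimensions of at least 8 voxels",
          class = "axotomo_domain_error")
  if (n_tracts < 0 || n_nuclei < 0)
    stopf("counts must be non-negative", class = "axotomo_domain_error")
  if (any(tract_radius_range <= 0) || any(nucleus_diameter_range <= 0))
    stopf("radii and diameters must be positive", class = "axotomo_domain_error")
  if (max(tract_radius_range) * 2 >= min(shape) * voxel_width)
    stopf("tract diameter exceeds the smallest volume dimension",
          class = "axotomo_domain_error")
  if (any(c(background_mu, tract_mu, nucleus_mu, vessel_mu) < 0))
    stopf("attenuation values must be non-negative",
          class = "axotomo_domain_error")
  structure(list(shape = shape, voxel_width = voxel_width,
                 n_tracts = as.integer(n_tracts),
                 tract_radius_range = tract_radius_range,
                 background_mu = background_mu, tract_mu = tract_mu,
                 nucleus_mu = nucleus_mu, n_nuclei = as.integer(n_nuclei),
                 nucleus_diameter_range = nucleus_diameter_range,
                 include_vessel = isTRUE(include_vessel),
                 vessel_mu = vessel_mu,
                 bifurcations = isTRUE(bifurcations),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d x %d x %d @ %.3g um, %d tracts ",
                     "(r %.1f-%.1f um), %d nuclei, vessel: %s, seed %d\n"),
              x$shape[1], x$shape[2], x$shape[3], x$voxel_width, x$n_tracts,
              x$tract_radius_range[1], x$tract_radius_range[2], x$n_nuclei,
              if (x$include_vessel) "yes" else "no", x$seed))
  invisible(x)
}

# ---- geometric helpers (voxel-unit coordinates, 1-based voxel centers) -----

# Densely resample a polyline to ~`step` spacing by arc length.
resample_polyline <- function(pts, step = 0.5) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < step) return(pts)
  sout <- seq(0, total, by = step)
  out <- sapply(1:3, function(d) stats::approx(s, pts[, d], xout = sout)$y)
  matrix(out, ncol = 3)
}

# Smooth centerline through jittered control points between A and E.
spline_centerline <- function(A, E, n_ctrl, jitter_yz, jitter_x) {
  f <- seq(0, 1, length.out = n_ctrl)
  ctrl <- outer(1 - f, A) + outer(f, E)
  if (n_ctrl > 2) {
    mid <- 2:(n_ctrl - 1)
    ctrl[mid, 1] <- ctrl[mid, 1] + rnorm(length(mid), 0, jitter_x)
    ctrl[mid, 2] <- ctrl[mid, 2] + rnorm(length(mid), 0, jitter_yz)
    ctrl[mid, 3] <- ctrl[mid, 3] + rnorm(length(mid), 0, jitter_yz)
  }
  tt <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  td <- seq(0, max(tt), length.out = 40 * n_ctrl)
  dense <- sapply(1:3, function(d)
    stats::spline(tt, ctrl[, d], xout = td, method = "natural")$y)
  resample_polyline(matrix(dense, ncol = 3), step = 0.5)
}

# Paint a tube of radius r (voxels) around centerline `pts` into the flat
# volume/label arrays; partial-volume boundary voxels get 8-point
# supersampled coverage fractions.  Returns the updated environment fields.
rasterize_tube <- function(env, pts, r, value, label_id) {
  dims <- env$dims
  Rpad <- ceiling(r) + 2L
  off <- as.matrix(expand.grid(x = -Rpad:Rpad, y = -Rpad:Rpad, z = -Rpad:Rpad))
  # candidate voxels: cubes around every other sample (step 1.0 covers gaps)
  take <- unique(c(seq(1, nrow(pts), by = 2L), nrow(pts)))
  ctr <- round(pts[take, , drop = FALSE])
  cand <- do.call(rbind, lapply(seq_len(nrow(ctr)), function(i)
    sweep(off, 2, ctr[i, ], `+`)))
  keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
    cand[, 2] >= 1 & cand[, 2] <= dims[2] &
    cand[, 3] >= 1 & cand[, 3] <= dims[3]
  cand <- cand[keep, , drop = FALSE]
  lin <- cand[, 1] + dims[1] * (cand[, 2] - 1 + dims[2] * (cand[, 3] - 1))
  dup <- duplicated(lin)
  cand <- cand[!dup, , drop = FALSE]
  lin <- lin[!dup]

  d <- min_dist_to_points_cpp(cand * 1.0, pts)$dist
  half <- sqrt(3) / 2  # half-diagonal of a voxel: conservative boundary band
  inside <- d <= r - half
  boundary <- !inside & d < r + half
  frac <- numeric(length(d))
  frac[inside] <- 1
  if (any(boundary)) {
    sub <- as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25), c(-0.25, 0.25)))
    bpts <- cand[boundary, , drop = FALSE]
    hits <- numeric(nrow(bpts))
    for (k in seq_len(8)) {
      dk <- min_dist_to_points_cpp(sweep(bpts, 2, sub[k, ], `+`), pts)$dist
      hits <- hits + (dk <= r)
    }
    frac[boundary] <- hits / 8
  }
  sel <- frac > 0
  lin <- lin[sel]; frac <- frac[sel]
  blend_at_cpp(env$vol, lin, frac, value)          # in-place: env owns vol
  set_label_at_cpp(env$lab, lin[frac >= 0.5], label_id)
  invisible(NULL)
}

rasterize_sphere <- function(env, center, r, value, label_id) {
  dims <- env$dims
  Rpad <- ceiling(r) + 1L
  rng <- lapply(1:3, function(d)
    max(1L, floor(center[d] - Rpad)):min(dims[d], ceiling(center[d] + Rpad)))
  g <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  d <- sqrt(colSums((t(g) - center)^2))
  half <- sqrt(3) / 2
  frac <- numeric(length(d))
  frac[d <= r - half] <- 1
  boundary <- d > r - half & d < r + half
  if (any(boundary)) {
    sub <- as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25), c(-0.25, 0.25)))
    bp <- g[boundary, , drop = FALSE]
    hits <- numeric(nrow(bp))
    for (k in seq_len(8)) {
      dk <- sqrt(colSums((t(sweep(bp, 2, sub[k, ], `+`)) - center)^2))
      hits <- hits + (dk <= r)
    }
    frac[boundary] <- hits / 8
  }
  sel <- frac > 0
  lin <- (g[sel, 1] + dims[1] * (g[sel, 2] - 1 + dims[2] * (g[sel, 3] - 1)))
  fr <- frac[sel]
  blend_at_cpp(env$vol, lin, fr, value)
  set_label_at_cpp(env$lab, lin[fr >= 0.5], label_id)
  invisible(NULL)
}

# would a sphere at `center` of radius r touch any labelled voxel?
sphere_site_free <- function(env, center, r) {
  dims <- env$dims
  Rpad <- ceiling(r) + 1L
  rng <- lapply(1:3, function(d)
    max(1L, floor(center[d] - Rpad)):min(dims[d], ceiling(center[d] + Rpad)))
  g <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  lin <- g[, 1] + dims[1] * (g[, 2] - 1 + dims[2] * (g[, 3] - 1))
  !any_label_at_cpp(env$lab, lin)
}

# ---- generator -------------------------------------------------------------

#' Generate a synthetic tissue phantom with ground truth
#'
#' Deterministic for a fixed spec (the seed lives in the spec).  Tracts are
#' non-self-intersecting spline tubes anchored on the +x face with mutual
#' clearance; placement that cannot satisfy the clearance after bounded
#' retries raises a generation error naming the failing tract.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (an [attenuation_volume()]) and
#'   `ground_truth` (list: `wire_model`, `labels` integer array where 0 is
#'   background, 1..n_tracts are tract ids, -1 nuclei, -2 vessel).
#' @examples
#' p <- generate_phantom(phantom_spec(shape = c(64, 64, 32), n_tracts = 3,
#'                                    n_nuclei = 5, seed = 7))
#' p$volume
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  dims <- spec$shape
  vw <- spec$voxel_width
  env <- new.env(parent = emptyenv())
  env$dims <- dims
  env$vol <- rep(spec$background_mu, prod(dims))
  env$lab <- integer(prod(dims))

  # vessel first: a thick gently-curved tube running left-to-right along the
  # bottom (low-z) edge of the field; the tract fan stays clear above it
  vr <- 12 / vw  # 12 um radius
  if (spec$include_vessel) {
    xv <- dims[1] * 0.8
    zv <- max(2, dims[3] * 0.06)
    yy <- seq(1, dims[2], length.out = 80)
    pts <- cbind(xv + (dims[1] * 0.03) * sin(yy / dims[2] * 2 * pi),
                 yy,
                 zv + pmax(1, dims[3] * 0.02) * cos(yy / dims[2] * 2 * pi))
    pts <- resample_polyline(pts, 0.5)
    rasterize_tube(env, pts, vr, spec$vessel_mu, VESSEL_LABEL)
    vessel_pts <- pts
  } else vessel_pts <- NULL

  r_vox <- numeric(spec$n_tracts)
  centerlines <- vector("list", spec$n_tracts)
  anchors <- matrix(NA_real_, 0, 3)
  all_samples <- NULL
  rmax_vox <- ceiling(max(spec$tract_radius_range) / vw)
  margin_y <- min(max(10, rmax_vox + 3), floor(dims[2] / 4))
  margin_z <- min(max(10, rmax_vox + 3), floor(dims[3] / 4))
  # keep the fan clear of the vessel lane at the bottom edge
  margin_z_lo <- if (spec$include_vessel)
    min(ceiling(max(2, dims[3] * 0.06) + vr + rmax_vox + 3),
        floor(dims[3] / 2.5)) else margin_z

  if (spec$n_tracts > 0) {
    for (k in seq_len(spec$n_tracts)) {
      r_um <- runif(1, spec$tract_radius_range[1], spec$tract_radius_range[2])
      r <- r_um / vw
      placed <- FALSE
      for (attempt in seq_len(150)) {
        A <- c(dims[1], runif(1, margin_y, dims[2] - margin_y),
               runif(1, margin_z_lo, dims[3] - margin_z))
        # anchor clearance: at least one tract diameter between anchors
        if (nrow(anchors) > 0) {
          dA <- sqrt(rowSums((anchors - matrix(A, nrow(anchors), 3,
                                               byrow = TRUE))^2))
          clear_anchor <- min(4 * max(spec$tract_radius_range) / vw,
                              min(dims[2], dims[3]) / 4)
          if (min(dA) < clear_anchor) next
        }
        # endpoints scatter across the deep half of the field ("various
        # positions"), which also spreads the fan apart
        E <- c(runif(1, 0.12, 0.55) * dims[1],
               runif(1, margin_y, dims[2] - margin_y),
               runif(1, margin_z_lo, dims[3] - margin_z))
        pts <- spline_centerline(A, E, n_ctrl = sample(4:8, 1),
                                 jitter_yz = min(dims[2], dims[3]) * 0.03,
                                 jitter_x = dims[1] * 0.01)
        # keep inside lateral bounds, monotone in x (no self-intersection)
        pts[, 2] <- pmin(pmax(pts[, 2], r + 2), dims[2] - r - 1)
        pts[, 3] <- pmin(pmax(pts[, 3], r + 2), dims[3] - r - 1)
        pts <- pts[pts[, 1] >= r + 2 & pts[, 1] <= dims[1], , drop = FALSE]
        if (nrow(pts) < 10 || any(diff(pts[, 1]) > 0.25)) next
        # clearance against existing tract centerlines and the vessel
        ok <- TRUE
        if (!is.null(all_samples)) {
          dmin <- min(min_dist_to_points_cpp(pts, all_samples)$dist)
          if (dmin < (r + max(r_vox[seq_len(k - 1)], 0) + 2.5)) ok <- FALSE
        }
        if (ok && !is.null(vessel_pts)) {
          dmin <- min(min_dist_to_points_cpp(pts, vessel_pts)$dist)
          if (dmin < (r + vr + 2.5)) ok <- FALSE
        }
        if (!ok) next
        r_vox[k] <- r
        centerlines[[k]] <- pts
        anchors <- rbind(anchors, A)
        all_samples <- rbind(all_samples, pts)
        placed <- TRUE
        break
      }
      if (!placed)
        stopf(paste0("could not place tract %d of %d after 150 attempts: ",
                     "inter-tract clearance constraint unsatisfiable for this ",
                     "spec/seed"), k, spec$n_tracts,
              class = "axotomo_generation_error")
    }
    for (k in seq_len(spec$n_tracts))
      rasterize_tube(env, centerlines[[k]], r_vox[k], spec$tract_mu, k)
  }

  # nuclei: only in unlabelled background
  placed_nuclei <- 0L
  if (spec$n_nuclei > 0) {
    for (k in seq_len(spec$n_nuclei)) {
      for (attempt in seq_len(100)) {
        r <- runif(1, spec$nucleus_diameter_range[1] / 2,
                   spec$nucleus_diameter_range[2] / 2) / vw
        ctr <- c(runif(1, r + 2, dims[1] - r - 1),
                 runif(1, r + 2, dims[2] - r - 1),
                 runif(1, r + 2, dims[3] - r - 1))
        if (!sphere_site_free(env, ctr, r + 1)) next
        rasterize_sphere(env, ctr, r, spec$nucleus_mu, NUCLEUS_LABEL)
        placed_nuclei <- placed_nuclei + 1L
        break
      }
    }
    if (placed_nuclei < spec$n_nuclei)
      stopf("could only place %d of %d nuclei without overlap",
            placed_nuclei, spec$n_nuclei, class = "axotomo_generation_error")
  }

  vol <- attenuation_volume(array(env$vol, dims), voxel_width = vw)
  vol <- add_provenance(vol, "generate_phantom",
                        parameters = list(n_tracts = spec$n_tracts,
                                          n_nuclei = spec$n_nuclei),
                        seed = spec$seed)

  truth <- phantom_truth_model(centerlines, r_vox, vw)
  list(volume = vol,
       ground_truth = list(wire_model = truth,
                           labels = array(env$lab, dims)))
}

# ground-truth wire model: centerline nodes every ~2 voxels, diameters = 2r
phantom_truth_model <- function(centerlines, r_vox, vw) {
  nodes <- list(); conns <- list(); offset <- 0L
  for (k in seq_along(centerlines)) {
    pts <- resample_polyline(centerlines[[k]], step = 2)
    n <- nrow(pts)
    nodes[[k]] <- tibble::tibble(
      trace = k, name = sprintf("%04d", seq_len(n) %% 10000L),
      x = index_to_um(pts[, 1], vw), y = index_to_um(pts[, 2], vw),
      z = index_to_um(pts[, 3], vw), diameter = 2 * r_vox[k] * vw)
    if (n > 1)
      conns[[k]] <- cbind(offset + seq_len(n - 1), offset + 2:n)
    offset <- offset + n
  }
  wire_model(if (length(nodes)) do.call(rbind, nodes) else NULL,
             if (length(conns)) do.call(rbind, conns) else NULL)
}
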