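# Shared fixtures, all built in code.

# a modest striatum-like phantom for unit tests (fast: ~1 s)
small_phantom <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 2L, shape = c(96L, 96L, 48L), n_tracts = 4L,
           n_nuclei = 10L, ...) {
    key <- paste(seed, paste(shape, collapse = "x"), n_tracts, n_nuclei,
                 sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_phantom(phantom_spec(
        shape = shape, n_tracts = n_tracts, n_nuclei = n_nuclei,
        seed = seed, ...))
    cache[[key]]
  }
})

# uniform disc slice: value mu inside radius r (pixels), 0 outside
disc_slice <- function(n, r, mu, cx = (n - 1) / 2, cy = (n - 1) / 2) {
  d2 <- outer((seq_len(n) - 1 - cx)^2, (seq_len(n) - 1 - cy)^2, `+`)
  matrix(ifelse(d2 <= r^2, mu, 0), n, n)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(m, sigma) {
  n <- 2 * ceiling(3 * sigma) + 1
  k <- dnorm(seq(-(n - 1) / 2, (n - 1) / 2), 0, sigma)
  k <- k / sum(k)
  pad <- (n - 1) / 2
  mp <- m[c(rep(1, pad), seq_len(nrow(m)), rep(nrow(m), pad)),
          c(rep(1, pad), seq_len(ncol(m)), rep(ncol(m), pad))]
  a <- apply(mp, 2, function(v) stats::filter(v, k, sides = 2))
  a <- t(apply(t(a), 2, function(v) stats::filter(v, k, sides = 2)))
  a[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))]
}

# knife-edge projection set: optical depth stepping 0 -> depth across the
# detector, at the propagation-imaging beam setting
knife_edge_set <- function(nd = 512L, depth = 1.0,
                           beam = beam_spec(energy_keV = 8, pixel_width = 0.5,
                                            propagation_distance_mm = 7,
                                            delta_beta = 400)) {
  profile <- c(rep(0, nd / 2), rep(depth, nd / 2))
  projection_set(array(profile, c(nd, 1, 1)), angles = 0,
                 kind = "line_integral", beam = beam)
}

# over/undershoot of an edge profile beyond its plateau values
edge_overshoot <- function(v, lo = 0, hi = 1) {
  max(0, max(v) - hi) + max(0, lo - min(v))
}

# straight tube along x in a small volume, for skeleton ground truth
straight_tube_volume <- function(dims = c(60L, 40L, 40L), radius_vox = 3,
                                 mu_bg = 1, mu_tube = 5, vw = 2.76) {
  yc <- (dims[2] + 1) / 2; zc <- (dims[3] + 1) / 2
  arr <- array(mu_bg, dims)
  for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    if ((j - yc)^2 + (k - zc)^2 <= radius_vox^2) arr[, j, k] <- mu_tube
  }
  attenuation_volume(arr, voxel_width = vw)
}
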