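# Threshold tracking, skeletonization, counting, evaluation.

test_that("the tracking floor resolves from sigma multiples or directly", {
  set.seed(1)
  v <- rnorm(8000)
  v <- v / sd(v) * 0.55 + 2.0            # sd exactly 0.55 cm^-1
  vol <- attenuation_volume(array(v, c(20, 20, 20)), 2.76)
  expect_equal(resolve_floor(trace_config(sigma_multiple = 6.0), vol), 3.3)
  expect_equal(resolve_floor(trace_config(sigma_multiple = 0), vol), 0)
  expect_equal(resolve_floor(trace_config(floor = 2.0), vol), 2.0)
  expect_error(trace_config(), class = "axotomo_argument_error")
  expect_error(trace_config(floor = 1, sigma_multiple = 6),
               class = "axotomo_argument_error")
})

test_that("a single straight tube traces to one accurate trace", {
  vol <- straight_tube_volume(radius_vox = 3)
  m <- trace_tracts(vol, trace_config(floor = 3.0, node_step = 6))
  expect_equal(n_traces(m), 1)
  vw <- vol$voxel_width
  # every node within one voxel of the true centerline (y = z = center)
  yc <- ((dim(vol$data)[2] + 1) / 2 - 1) * vw
  zc <- ((dim(vol$data)[3] + 1) / 2 - 1) * vw
  off <- sqrt((m$nodes$y - yc)^2 + (m$nodes$z - zc)^2)
  expect_lt(max(off), vw)
  # diameters within one voxel of the tube diameter (2 x 3 voxels)
  expect_lt(max(abs(m$nodes$diameter - 6 * vw)), 1.01 * vw)
})

test_that("volumes with nothing above the floor give an empty model", {
  vol <- attenuation_volume(array(1.0, c(16, 16, 16)), 2.76)
  m <- trace_tracts(vol, trace_config(floor = 3.3))
  expect_equal(n_traces(m), 0)
  bad <- attenuation_volume(array(c(NA, rep(1, 4095)), c(16, 16, 16)), 2.76)
  expect_error(trace_tracts(bad, trace_config(floor = 0.5)),
               class = "axotomo_data_error")
})

test_that("tracing a noise-free phantom recovers every tract", {
  p <- small_phantom(seed = 2)
  m <- trace_tracts(p$volume, trace_config(floor = 5.2))
  expect_equal(n_traces(m), 4)
  ev <- evaluate_model(m, p$ground_truth$wire_model,
                       tolerance = 2 * p$volume$voxel_width)
  expect_gte(ev$recall, 0.95)
  expect_true(all(ev$per_tract$recall >= 0.9))
  # deterministic: a second run yields the identical model
  m2 <- trace_tracts(p$volume, trace_config(floor = 5.2))
  expect_identical(m$nodes, m2$nodes)
  expect_identical(m$connections, m2$connections)
})

test_that("medial axes of tube phantoms stay within a voxel of the centerline", {
  p <- small_phantom(seed = 2)
  m <- trace_tracts(p$volume, trace_config(floor = 5.2, node_step = 3))
  truth <- p$ground_truth$wire_model
  vw <- p$volume$voxel_width
  for (tr in seq_len(n_traces(m))) {
    found <- as.matrix(m$nodes[m$nodes$trace == tr, c("x", "y", "z")])
    best <- Inf
    for (tt in seq_len(n_traces(truth))) {
      ctr <- as.matrix(truth$nodes[truth$nodes$trace == tt, c("x", "y", "z")])
      d <- axotomo:::min_dist_to_points_cpp(found, ctr)$dist
      best <- min(best, max(d))
    }
    expect_lt(best, sqrt(3) * vw)  # within a voxel diagonal everywhere
  }
})

test_that("raising the floor never grows the thresholded voxel set", {
  p <- small_phantom(seed = 2)
  floors <- c(4.2, 5.0, 5.8, 6.4)
  counts <- vapply(floors, function(f) sum(p$volume$data >= f), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("section counts match the tracts crossing the plane", {
  p <- small_phantom(seed = 2)
  x_near_anchor <- dim(p$volume$data)[1] - 6
  n <- count_tracts_in_section(p$volume, floor = 5.2, min_area = 2,
                               x = x_near_anchor)
  truth_n <- length(setdiff(unique(as.vector(
    p$ground_truth$labels[x_near_anchor, , ])), c(0L, -1L, -2L)))
  expect_equal(n, truth_n)
  expect_equal(count_tracts_in_section(matrix(0, 32, 32), floor = 1), 0)
  expect_equal(count_tracts_in_section(p$volume, floor = 99, z = 10), 0)
})

test_that("evaluation scores identity, emptiness and mismatched conventions", {
  p <- small_phantom(seed = 2)
  truth <- p$ground_truth$wire_model
  self <- evaluate_model(truth, truth, tolerance = 1)
  expect_equal(self$recall, 1)
  expect_equal(self$precision, 1)
  expect_equal(self$mean_deviation, 0, tolerance = 1e-9)
  empty <- wire_model()
  ev <- evaluate_model(empty, truth, tolerance = 5)
  expect_equal(ev$recall, 0)
  other <- truth
  other$convention <- coordinate_convention(x_axis = "anteroposterior",
                                            z_axis = "dorsoventral")
  expect_error(evaluate_model(other, truth),
               class = "axotomo_convention_error")
})

test_that("wire-model invariants are enforced", {
  nodes <- tibble::tibble(trace = c(1L, 1L, 2L), name = c("a", "b", "a"),
                          x = c(0, 1, 5), y = c(0, 1, 5), z = c(0, 1, 5),
                          diameter = c(1, 1, 1))
  expect_silent(wire_model(nodes, rbind(c(1, 2))))
  # trace 1 disconnected without its connection
  expect_error(wire_model(nodes, NULL), class = "axotomo_model_error")
  bad_serial <- nodes; bad_serial$trace <- c(1L, 1L, 3L)
  expect_error(wire_model(bad_serial, rbind(c(1, 2))),
               class = "axotomo_model_error")
  dup <- nodes; dup$name <- c("a", "a", "b")
  expect_error(wire_model(dup, rbind(c(1, 2))), class = "axotomo_model_error")
  expect_error(wire_model(nodes, rbind(c(1, 9))), class = "axotomo_model_error")
})
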