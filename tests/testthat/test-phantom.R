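# Synthetic phantom generator.

test_that("an empty scene is a constant background volume", {
  sp <- phantom_spec(shape = c(32, 32, 16), n_tracts = 0, n_nuclei = 0,
                     include_vessel = FALSE, seed = 1)
  p <- generate_phantom(sp)
  expect_true(all(p$volume$data == sp$background_mu))
  expect_equal(n_traces(p$ground_truth$wire_model), 0)
  expect_true(all(p$ground_truth$labels == 0L))
})

test_that("the ground truth contains exactly the requested tracts, reproducibly", {
  p1 <- small_phantom(seed = 2)
  expect_equal(n_traces(p1$ground_truth$wire_model), 4)
  tract_ids <- setdiff(unique(as.vector(p1$ground_truth$labels)), c(0L, -1L, -2L))
  expect_setequal(tract_ids, 1:4)
  p2 <- generate_phantom(phantom_spec(shape = c(96L, 96L, 48L), n_tracts = 4L,
                                      n_nuclei = 10L, seed = 2L))
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$ground_truth$labels, p2$ground_truth$labels)
  expect_identical(p1$ground_truth$wire_model$nodes,
                   p2$ground_truth$wire_model$nodes)
})

test_that("the voxel histogram mode sits within one bin of the background", {
  p <- small_phantom(seed = 2)
  h <- attenuation_histogram(p$volume)
  expect_lte(abs(h$mode_center - 3.9), 0.1)
  # oracle: background voxels are the outright majority of the label volume
  expect_gt(mean(p$ground_truth$labels == 0L), 0.5)
})

test_that("rendering-range masks select the expected voxel sets", {
  p <- small_phantom(seed = 2)
  sp <- phantom_spec()  # default attenuation levels
  v <- p$volume
  const <- attenuation_volume(array(2.5, c(8, 8, 2)), 1)
  expect_true(all(render_range_mask(const, 1.5, 3.5)))
  expect_false(any(render_range_mask(v, max(v$data) + 1, max(v$data) + 2)))
  expect_error(render_range_mask(v, 3, 3), class = "axotomo_argument_error")
  # bracketing the tract value picks out exactly the tract-labelled voxels
  lo <- sp$background_mu + (7 / 16) * (sp$tract_mu - sp$background_mu)
  mask <- render_range_mask(v, lo, sp$tract_mu + 1e-9)
  expect_equal(sum(mask), sum(p$ground_truth$labels > 0L))
})

test_that("tract centerlines stay inside their labelled tubes", {
  p <- small_phantom(seed = 2)
  wm <- p$ground_truth$wire_model
  vw <- p$volume$voxel_width
  idx <- cbind(round(wm$nodes$x / vw + 1), round(wm$nodes$y / vw + 1),
               round(wm$nodes$z / vw + 1))
  labs <- p$ground_truth$labels[idx]
  expect_true(all(labs == wm$nodes$trace))
})

test_that("doubling the nucleus count about doubles the nucleus voxel count", {
  p1 <- generate_phantom(phantom_spec(shape = c(96, 96, 48), n_tracts = 0,
                                      n_nuclei = 30, include_vessel = FALSE,
                                      seed = 9))
  p2 <- generate_phantom(phantom_spec(shape = c(96, 96, 48), n_tracts = 0,
                                      n_nuclei = 60, include_vessel = FALSE,
                                      seed = 9))
  n1 <- sum(p1$ground_truth$labels == -1L)
  n2 <- sum(p2$ground_truth$labels == -1L)
  expect_gt(n2 / n1, 1.5)
  expect_lt(n2 / n1, 2.5)
})

test_that("infeasible packing raises a generation error naming the constraint", {
  sp <- phantom_spec(shape = c(24, 24, 12), n_tracts = 40,
                     tract_radius_range = c(8, 9), n_nuclei = 0,
                     include_vessel = FALSE, seed = 1)
  expect_error(generate_phantom(sp), regexp = "clearance",
               class = "axotomo_generation_error")
})
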