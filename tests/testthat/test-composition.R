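# Tissue attenuation composition model.

test_that("the composition chain reproduces the printed dried-brain predictions", {
  water <- attenuation_table("water", c(6, 8), c(24.63, 10.37))
  mu_rho_water <- interpolate_mass_attenuation(water, 7.13)
  expect_equal(round_half_up(mu_rho_water, 1), 16.6)

  brain <- tissue_composition("whole brain", 0.80, 1.03, 0.37, 0.58)
  myelin <- tissue_composition("myelin", 0.40, 1.03, 0.71, 0.44)

  mu_wet <- linear_attenuation(16.7, 1.03)
  expect_equal(round_half_up(mu_wet, 1), 17.2)

  expect_equal(round_half_up(dried_attenuation(mu_wet, brain, 16.6), 1), 3.9)
  expect_equal(round_half_up(dried_attenuation(mu_wet, myelin, 16.6), 1), 10.6)

  expect_equal(round_half_up(phospholipid_density(myelin), 3), 0.193)
  expect_equal(round_half_up(phospholipid_density(brain), 3), 0.044)

  pl <- phospholipid_spec(750, 1)
  p <- default_phosphorus()
  expect_equal(round_half_up(phosphorus_attenuation(0.193, pl, p), 2), 0.87)
  expect_equal(round_half_up(phosphorus_attenuation(0.044, pl, p), 2), 0.20)
})

test_that("interpolation is linear in energy and refuses extrapolation", {
  water <- attenuation_table("water", c(6, 8), c(24.63, 10.37))
  # two-point line oracle evaluated by hand
  line <- function(e) 24.63 + (10.37 - 24.63) * (e - 6) / 2
  expect_equal(interpolate_mass_attenuation(water, 7.13), line(7.13))
  expect_equal(interpolate_mass_attenuation(water, 7.13), 16.573, tolerance = 1e-4)
  # identity at the knots
  expect_equal(interpolate_mass_attenuation(water, 6), 24.63)
  expect_equal(interpolate_mass_attenuation(water, 8), 10.37)
  # constant tables stay constant
  flat <- attenuation_table("flat", c(5, 9), c(3.3, 3.3))
  expect_equal(interpolate_mass_attenuation(flat, 6.2), 3.3)
  expect_error(interpolate_mass_attenuation(water, 5.9),
               class = "axotomo_range_error")
  expect_error(interpolate_mass_attenuation(water, 8.1),
               class = "axotomo_range_error")
})

test_that("interpolation agrees with a brute-force line through the bracketing knots", {
  set.seed(7)
  for (i in 1:40) {
    ne <- sample(2:6, 1)
    e <- sort(runif(ne, 4, 20))
    while (any(diff(e) < 1e-3)) e <- sort(runif(ne, 4, 20))
    mu <- runif(ne, 1, 60)
    tab <- attenuation_table("rand", e, mu)
    q <- runif(1, min(e), max(e))
    hi <- which(e >= q)[1]
    if (hi == 1) hi <- 2
    lo <- hi - 1
    oracle <- mu[lo] + (mu[hi] - mu[lo]) * (q - e[lo]) / (e[hi] - e[lo])
    expect_equal(interpolate_mass_attenuation(tab, q), oracle, tolerance = 1e-10)
  }
})

test_that("water removal is monotone in water content and guards its domain", {
  comp_w <- function(w) tissue_composition("t", w, 1.03, 0.4, 0.4)
  mus <- vapply(seq(0, 0.9, by = 0.1),
                function(w) dried_attenuation(17.2, comp_w(w), 16.6), 0)
  expect_true(all(diff(mus) < 0))
  expect_equal(dried_attenuation(5.0, comp_w(0), 16.6), 5.0)  # no water
  # w = 1.05 would be invalid composition; w high enough to go negative errors
  expect_error(dried_attenuation(10, comp_w(0.9), 16.6),
               class = "axotomo_composition_error")
  expect_error(linear_attenuation(-1, 1), class = "axotomo_domain_error")
  # density-weighted variant subtracts more for rho > 1
  expect_lt(dried_attenuation(17.2, comp_w(0.8), 16.6, density_weighted = TRUE),
            dried_attenuation(17.2, comp_w(0.8), 16.6))
})

test_that("phospholipid quantities are linear in every fraction", {
  base <- tissue_composition("t", 0.4, 1.03, 0.71, 0.44)
  scaled <- tissue_composition("t", 0.4, 1.03, 0.71 * 0.5, 0.44)
  expect_equal(phospholipid_density(scaled), phospholipid_density(base) * 0.5)
  none <- tissue_composition("t", 0.4, 1.03, 0, 0.44)
  expect_equal(phospholipid_density(none), 0)
  expect_equal(phosphorus_attenuation(0, phospholipid_spec(),
                                      default_phosphorus()), 0)
  # linear in the phospholipid density
  p <- default_phosphorus(); pl <- phospholipid_spec()
  expect_equal(phosphorus_attenuation(0.2, pl, p),
               2 * phosphorus_attenuation(0.1, pl, p))
})

test_that("the shipped database drives a full derivation report", {
  rep_my <- composition_report("myelin")
  expect_s3_class(rep_my, "tbl_df")
  get <- function(r, q, col = "printed") r[[col]][r$quantity == q]
  expect_equal(get(rep_my, "linear_attenuation_wet"), 17.2)
  expect_equal(get(rep_my, "linear_attenuation_dried"), 10.6)
  expect_equal(get(rep_my, "phospholipid_density"), 0.193)
  expect_equal(get(rep_my, "phosphorus_attenuation"), 0.87)
  rep_wb <- composition_report("whole_brain")
  expect_equal(get(rep_wb, "linear_attenuation_dried"), 3.9)
  expect_equal(get(rep_wb, "phospholipid_density"), 0.044)
  expect_equal(get(rep_wb, "phosphorus_attenuation"), 0.20)
  # resin is a stated linear coefficient, present in the material database
  mats <- default_materials()
  expect_equal(mats$value[mats$material == "epoxy_resin"], 9.0)
  expect_error(composition_report("liver"), class = "axotomo_domain_error")
})
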