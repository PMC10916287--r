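lys <- crystallization_recipe(20, 1, 4)  # 4 mg/ml final, high-salt lysozyme

test_that("final concentration follows the mixing parts", {
  expect_equal(final_concentration(lys), 4)
  pdx <- crystallization_recipe(12, 1, 2)  # 1:1:1 protein:seed:liquor
  expect_equal(final_concentration(pdx), 4)
  expect_equal(final_concentration(crystallization_recipe(33, 1, 0)), 33)
})

test_that("mass-balance prediction gives micrometre crystals from picolitre droplets", {
  p <- predict_crystal_length(0.89, lys, k = 1)
  expect_equal(p$crystal_volume_um3, 4.45)
  expect_equal(p$length_um, 3.19, tolerance = 1e-3)
  expect_false(p$no_growth)
  p15 <- predict_crystal_length(194, lys, k = 15)
  expect_equal(p15$length_um, 7.78, tolerance = 1e-3)
  # saturated solution: flagged, zero size
  sat <- crystallization_recipe(20, 1, 4, residual_solubility_mg_ml = 4)
  psat <- predict_crystal_length(10, sat, k = 1)
  expect_true(psat$no_growth)
  expect_equal(psat$length_um, 0)
})

test_that("crystal length scales as the cube root of droplet volume at fixed k", {
  p1 <- predict_crystal_length(5, lys)
  p8 <- predict_crystal_length(40, lys)
  expect_equal(p8$length_um, 2 * p1$length_um, tolerance = 1e-12)
  for (pair in list(c(0.89, 10), c(1, 194), c(3, 81), c(10, 500), c(0.1, 754))) {
    r <- predict_crystal_length(pair[1], lys)$length_um /
      predict_crystal_length(pair[2], lys)$length_um
    expect_equal(r, (pair[1] / pair[2])^(1 / 3), tolerance = 1e-12)
  }
})

test_that("prediction conserves protein mass", {
  for (k in c(1, 3, 15)) {
    p <- predict_crystal_length(194, lys, k = k)
    mass_lhs <- k * p$width_um^2 * p$length_um *
      lys$crystal_packing_density_mg_ml
    mass_rhs <- 194 * 1000 * (final_concentration(lys) -
                                lys$residual_solubility_mg_ml)
    expect_equal(mass_lhs, mass_rhs, tolerance = 1e-9)
  }
})

test_that("volume_for_length inverts the mass balance", {
  v <- volume_for_length(3.19, lys)
  expect_equal(predict_crystal_length(v, lys)$length_um, 3.19, tolerance = 1e-9)
})

test_that("seed dilution scales length by the cube root (upper-bound model)", {
  expect_equal(seed_dilution_length(11, 1), 11)
  expect_equal(seed_dilution_length(11, 10), 23.7, tolerance = 1e-3)
  expect_equal(seed_dilution_length(11, 100), 51.1, tolerance = 1e-3)
  expect_error(seed_dilution_length(11, 0.5), ">= 1")
})

test_that("droplet diameter caps the crystal axial ratio", {
  r <- axial_ratio_cap(20, 1, 10)
  expect_equal(r$length_um, 10)
  expect_equal(r$axial_ratio, 10)
  expect_true(r$capped)
  r2 <- axial_ratio_cap(7, 2, 50)
  expect_equal(r2$length_um, 7)
  expect_equal(r2$axial_ratio, 3.5)
  expect_false(r2$capped)
  r3 <- axial_ratio_cap(14, 2, 8)
  expect_equal(r3$length_um, 8)
  expect_equal(r3$axial_ratio, 4)
  # monotone non-decreasing in droplet diameter
  caps <- vapply(c(5, 8, 12, 14, 20, 30),
                 function(d) axial_ratio_cap(14, 2, d)$length_um, numeric(1))
  expect_true(all(diff(caps) >= 0))
})

test_that("into-crystal diffusion time matches a Crank-Nicolson oracle within 2%", {
  pairs <- list(c(1, 1000), c(1, 100), c(0.5, 500), c(2, 1000), c(3, 300),
                c(1.5, 50))
  for (p in pairs) {
    got <- diffusion_time_into_crystal(p[1], p[2], 0.5)
    want <- oracle_slab_center_time(p[1], p[2], 0.5, n_nodes = 2000,
                                    n_steps = 3000)
    expect_equal(got, want, tolerance = 0.02)
  }
  expect_equal(diffusion_time_into_crystal(1, 1000, 0.5), 0.379,
               tolerance = 1e-3)
  # t scales as travel^2 / D
  expect_equal(diffusion_time_into_crystal(2, 1000, 0.5),
               4 * diffusion_time_into_crystal(1, 1000, 0.5), tolerance = 1e-9)
  expect_lt(diffusion_time_into_crystal(1, 1e9, 0.5), 1e-6)
  expect_error(diffusion_time_into_crystal(1, 1000, 1.2), "center_fraction")
})

test_that("diffusivity_from_time inverts the series solution", {
  expect_equal(diffusivity_from_time(0.4, 1, 0.5), 947, tolerance = 1e-2)
  d <- diffusivity_from_time(diffusion_time_into_crystal(1.3, 650, 0.5), 1.3, 0.5)
  expect_equal(d, 650, tolerance = 1e-9)
})

test_that("length-vs-diameter helper fits an unconstrained line", {
  d <- c(10, 20, 30, 40)
  l <- 0.5 * d + 1 + c(0.01, -0.02, 0.02, -0.01)
  fit <- fit_length_diameter(l, d)
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.02)
})
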