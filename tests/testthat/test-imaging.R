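test_that("a blank image yields no detections", {
  blank <- matrix(0.35, 128, 128)
  det <- detect_droplets(blank, 0.5)
  expect_equal(nrow(det), 0)
  expect_equal(nrow(measure_crystals(blank, det, 0.5)), 0)
})

test_that("noise-free synthetic fields are detected completely and accurately", {
  im <- imaging_config(pixel_size_um = 0.5, image_size = c(900, 900),
                       noise_sd = 0, seed = 11)
  fld <- gen_droplet_field(100, 20, size_cv = 0.03, lam = 0.5, imaging = im)
  det <- detect_droplets(fld$image, 0.5)
  expect_equal(nrow(det), 100)
  match_idx <- vapply(seq_len(nrow(det)), function(i) {
    which.min((fld$truth$center_x_px - det$center_x_px[i])^2 +
                (fld$truth$center_y_px - det$center_y_px[i])^2)
  }, integer(1))
  expect_equal(length(unique(match_idx)), 100)
  rel_err <- det$diameter_um / fld$truth$diameter_um[match_idx] - 1
  expect_lt(max(abs(rel_err)), 0.02)     # every droplet within 2% of truth
  expect_lt(abs(mean(rel_err)), 0.01)    # bias <= 1% (droplets ~40 px across)
  expect_true(all(det$circularity >= 0.8))
  # deterministic for fixed parameters
  expect_identical(det, detect_droplets(fld$image, 0.5))
})

test_that("watershed separates tangent droplets", {
  img <- matrix(0.35, 160, 160)
  cfg <- imaging_config(pixel_size_um = 0.5, image_size = c(160, 160))
  img <- dropxtal:::render_droplet(img, 50, 80, 25, NULL, cfg)
  img <- dropxtal:::render_droplet(img, 100, 80, 25, NULL, cfg)
  det <- detect_droplets(img, 0.5)
  expect_equal(nrow(det), 2)
  expect_equal(sort(det$center_x_px), c(50, 100), tolerance = 0.05)
})

test_that("rod crystals are measured by their rotated bounding box", {
  # one 7 x 2 um rod at 30 degrees inside a droplet, zero noise
  cfg <- imaging_config(pixel_size_um = 0.25, image_size = c(200, 200),
                        noise_sd = 0)
  img <- matrix(cfg$background_level, 200, 200)
  rod <- data.frame(center_x_px = 100, center_y_px = 100,
                    half_len_px = 3.5 / 0.25, half_wid_px = 1 / 0.25,
                    orientation_deg = 30)
  img <- dropxtal:::render_droplet(img, 100, 100, 80, rod, cfg)
  det <- detect_droplets(img, 0.25)
  expect_equal(nrow(det), 1)
  cry <- measure_crystals(img, det, 0.25)
  expect_equal(nrow(cry), 1)
  expect_equal(cry$length_um, 7, tolerance = 0.5 / 7)
  expect_equal(cry$width_um, 2, tolerance = 0.5 / 2)
  expect_equal(cry$orientation_deg, 30, tolerance = 0.1)
  # droplet with no crystal: empty result
  img0 <- matrix(cfg$background_level, 200, 200)
  img0 <- dropxtal:::render_droplet(img0, 100, 100, 80, NULL, cfg)
  det0 <- detect_droplets(img0, 0.25)
  expect_equal(nrow(measure_crystals(img0, det0, 0.25)), 0)
})

test_that("two disjoint rods in one droplet give two measurements", {
  cfg <- imaging_config(pixel_size_um = 0.25, image_size = c(200, 200),
                        noise_sd = 0)
  img <- matrix(cfg$background_level, 200, 200)
  rods <- data.frame(center_x_px = c(70, 130), center_y_px = c(80, 120),
                     half_len_px = 14, half_wid_px = 4,
                     orientation_deg = c(0, 110))
  img <- dropxtal:::render_droplet(img, 100, 100, 80, rods, cfg)
  det <- detect_droplets(img, 0.25)
  cry <- measure_crystals(img, det, 0.25)
  expect_equal(nrow(cry), 2)
  expect_equal(cry$droplet_id, c(1, 1))
})

test_that("population summaries recover generator parameters on truth tables", {
  im <- imaging_config(pixel_size_um = 0.5, image_size = c(1000, 1000),
                       noise_sd = 0, seed = 8)
  fld <- gen_droplet_field(200, 20, size_cv = 0.03, lam = 0.3, imaging = im)
  s <- summarize_population(fld$truth, fld$truth_crystals)
  expect_equal(s$lambda_fit$lambda, mean(fld$truth$n_crystals))
  expect_lt(abs(s$droplet_diameter_mean_um - 20), 0.5)
  expect_lt(abs(s$droplet_diameter_cv - 0.03), 0.01)
})

test_that("summary edge cases behave as documented", {
  droplets <- data.frame(droplet_id = 1:100, diameter_um = rep(12, 100))
  crystals <- data.frame(droplet_id = 1:10, length_um = rep(3, 10))
  s <- summarize_population(droplets, crystals)
  expect_equal(s$lambda_fit$lambda, 0.1)   # occupancy {0:90, 1:10}
  one <- summarize_population(droplets, crystals[1, ])
  expect_false(one$length_cv_defined)
  expect_true(is.na(one$crystal_length_cv))
  expect_error(summarize_population(droplets[0, ], crystals), "at least one")
})
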