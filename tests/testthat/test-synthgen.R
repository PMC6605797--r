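test_that("identical config and seed give bit-identical images and truth", {
  cfg <- synth_config(seed = 42, noise_sd = 25, poisson = TRUE)
  a <- generate_image(cfg)
  b <- generate_image(cfg)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$vesicles, b$truth$vesicles)
})

test_that("noise level changes pixels but never the ground truth", {
  base <- synth_config(seed = 7, noise_sd = 0)
  noisy <- synth_config(seed = 7, noise_sd = 40)
  a <- generate_image(base)
  b <- generate_image(noisy)
  expect_identical(a$truth$vesicles, b$truth$vesicles)
  expect_false(identical(a$image$channels$red, b$image$channels$red))
})

test_that("all-perinuclear config places every vesicle near the nucleus boundary", {
  cfg <- synth_config(seed = 3, zone_intensity_fractions = c(1, 0, 0),
                      noise_sd = 0, n_vesicles_per_cell = 10)
  out <- generate_image(cfg)
  v <- out$truth$vesicles
  expect_true(all(v$zone == "perinuclear"))
  expect_true(all(v$min_distance_px * cfg$pixel_size_um <= 2))
  expect_equal(out$truth$zone_fractions$fraction,
               c(1, 0, 0), tolerance = 1e-9)
})

test_that("zero vesicles leave only background and noise in vesicle channels", {
  cfg <- synth_config(seed = 2, n_vesicles_per_cell = 0, noise_sd = 0,
                      background_level = 120)
  out <- generate_image(cfg)
  expect_true(all(out$image$channels$red == 120))
  expect_equal(nrow(out$truth$vesicles), 0)
})

test_that("ground-truth fractions are recomputable from per-vesicle records", {
  cfg <- synth_config(seed = 11, zone_intensity_fractions = c(0.5, 0.3, 0.1),
                      noise_sd = 15)
  out <- generate_image(cfg)
  rec <- recompute_zone_fractions(out$truth)
  expect_equal(rec$fraction, out$truth$zone_fractions$fraction)
  expect_equal(rec$intensity, out$truth$zone_fractions$intensity)
})

test_that("noise-free rendering conserves per-vesicle intensity mass", {
  for (shape in c("spot", "rod")) {
    cfg <- synth_config(seed = 5, vesicle_shape = shape, noise_sd = 0,
                        n_vesicles_per_cell = 8, background_level = 0,
                        zone_intensity_fractions = c(0.4, 0.3, 0.3))
    out <- generate_image(cfg)
    # rendered truth intensities within 0.5% of the configured budget
    expect_equal(out$truth$vesicles$intensity,
                 rep(cfg$vesicle_intensity, nrow(out$truth$vesicles)),
                 tolerance = 0.005)
    # and the noise-free channel total matches vesicle + diffuse mass
    expect_equal(sum(out$image$channels$red),
                 sum(out$truth$vesicles$intensity) +
                   out$truth$zone_fractions$diffuse_total[1],
                 tolerance = 0.005)
  }
})

test_that("impossible placement demands fail with an explicit error", {
  cfg <- synth_config(seed = 1, image_size_px = c(96, 96), n_cells = 1,
                      n_vesicles_per_cell = 500,
                      zone_intensity_fractions = c(1, 0, 0),
                      min_separation_um = 2)
  expect_error(generate_image(cfg), "placement failure")
})

test_that("config invariants are enforced", {
  expect_error(synth_config(zone_intensity_fractions = c(0.8, 0.3, 0.2)))
  expect_error(synth_config(zone_intensity_fractions = c(-0.1, 0.5, 0.2)))
  expect_error(synth_config(coloc_fraction = 1.5))
  expect_error(synth_config(pixel_size_um = 0))
})

test_that("generate_group writes the expected files deterministically", {
  cfg <- synth_config(image_size_px = c(96, 96), n_cells = 1,
                      n_vesicles_per_cell = 4, noise_sd = 10)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man <- generate_group(cfg, n_images = 2, n_repeats = 2, dir1, seed = 9)
  expect_equal(nrow(man), 4)
  tifs <- list.files(dir1, pattern = "\\.tif$", recursive = TRUE)
  expect_length(tifs, 4)
  expect_true(file.exists(file.path(dir1, "ground_truth.csv")))

  generate_group(cfg, n_images = 2, n_repeats = 2, dir2, seed = 9)
  for (f in tifs) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
  expect_error(generate_group(cfg, n_images = 2, n_repeats = 0, dir1), ">= 1")
})
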