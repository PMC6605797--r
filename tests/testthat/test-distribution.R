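test_that("particle measurement reports min distance, IntDen, area, centroid", {
  labels <- matrix(0L, 4, 4)
  labels[2, 1:3] <- 1L
  channel <- matrix(0, 4, 4); channel[2, 1:3] <- c(10, 20, 30)
  dmap <- matrix(9, 4, 4); dmap[2, 1:3] <- c(4, 5, 6)
  pt <- measure_particles(labels, channel, dmap)
  expect_equal(pt$min_distance_px, 4)
  expect_equal(pt$integrated_intensity, 60)
  expect_equal(pt$area_px, 3)
  expect_equal(pt$centroid_row, 2)
  expect_equal(pt$centroid_col, 2)

  empty <- measure_particles(matrix(0L, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(nrow(empty), 0)
  expect_error(measure_particles(matrix(0L, 3, 3), matrix(0, 2, 2),
                                 matrix(0, 3, 3)), "shape")
})

test_that("zone assignment follows the 2/5 um bins with nearer-nucleus tie-break", {
  expect_equal(as.character(assign_zone(8, 0.2)), "perinuclear")    # 1.6 um
  expect_equal(as.character(assign_zone(0, 0.2)), "perinuclear")
  expect_equal(as.character(assign_zone(30, 0.2)), "periphery")     # 6 um
  expect_equal(as.character(assign_zone(15, 0.2)), "intermediate")  # 3 um
  # boundary values go to the nearer-nucleus zone
  expect_equal(as.character(assign_zone(10, 0.2)), "perinuclear")   # exactly 2
  expect_equal(as.character(assign_zone(25, 0.2)), "intermediate")  # exactly 5
  expect_error(assign_zone(-1, 0.2), ">= 0")
  expect_error(assign_zone(5, 0), "> 0")
})

test_that("zone distribution normalizes by total image fluorescence", {
  pt <- data.frame(label = 1:2, min_distance_px = c(5, 40),
                   integrated_intensity = c(60, 40), area_px = c(3, 3))
  zd <- zone_distribution(pt, total_image_intensity = 200, pixel_size_um = 0.2)
  expect_equal(zd$perinuclear, 0.3)
  expect_equal(zd$intermediate, 0)
  expect_equal(zd$periphery, 0.2)
  expect_equal(zd$n_particles, 2)

  empty <- zone_distribution(pt[0, ], 100, 0.2)
  expect_equal(as.numeric(empty[1, c("perinuclear", "intermediate", "periphery")]),
               c(0, 0, 0))
  expect_error(zone_distribution(pt, 0, 0.2), "> 0")
})

test_that("hierarchical aggregation averages images within repeats then repeats", {
  d <- data.frame(repeat_id = c(1, 1, 2, 3),
                  perinuclear = c(0.1, 0.3, 0.3, 0.4),
                  intermediate = c(0.2, 0.2, 0.2, 0.2),
                  periphery = c(0.5, 0.3, 0.4, 0.3))
  gs <- aggregate_zone_distributions(d)
  # repeat means for perinuclear: 0.2, 0.3, 0.4 -> mean 0.3, SEM sd/sqrt(3)
  peri <- gs[gs$zone == "perinuclear", ]
  expect_equal(peri$mean, 0.3)
  expect_equal(peri$sem, sd(c(0.2, 0.3, 0.4)) / sqrt(3))
  expect_equal(peri$n_repeats, 3)

  # permuting image order changes nothing
  gs2 <- aggregate_zone_distributions(d[c(3, 1, 4, 2), ])
  expect_equal(gs2$mean, gs$mean)
  expect_equal(gs2$sem, gs$sem)

  expect_warning(single <- aggregate_zone_distributions(d[1:2, ]), "single")
  expect_equal(single$sem, rep(0, 3))
})

test_that("pipeline is deterministic and scale-invariant in the vesicle channel", {
  cfg <- scenario_distribution("uniform", seed = 21)
  out <- generate_image(cfg)
  r1 <- run_distribution_pipeline(out$image)
  r2 <- run_distribution_pipeline(out$image)
  expect_identical(r1, r2)

  # multiplying the vesicle channel by a constant leaves fractions unchanged
  scaled <- out$image
  scaled$channels$red <- scaled$channels$red * 0.5
  r3 <- run_distribution_pipeline(scaled)
  zcols <- c("perinuclear", "intermediate", "periphery")
  expect_equal(as.numeric(r3[1, zcols]), as.numeric(r1[1, zcols]),
               tolerance = 0.02)
})

test_that("pipeline returns zero fractions for an empty vesicle channel", {
  cfg <- synth_config(seed = 4, n_vesicles_per_cell = 0, noise_sd = 0)
  out <- generate_image(cfg)
  res <- run_distribution_pipeline(out$image)
  expect_equal(as.numeric(res[1, c("perinuclear", "intermediate", "periphery")]),
               c(0, 0, 0))
})

test_that("fractions sum to at most 1 and match the segmented share of intensity", {
  cfg <- scenario_distribution("clustered", seed = 8)
  out <- generate_image(cfg)
  res <- run_distribution_pipeline(out$image, keep_intermediates = TRUE)
  zcols <- c("perinuclear", "intermediate", "periphery")
  fsum <- sum(res$distribution[1, zcols])
  expect_lte(fsum, 1)
  sub <- subtract_background(out$image$channels$red)
  expect_equal(fsum,
               sum(res$particles$red$integrated_intensity) / sum(sub),
               tolerance = 1e-9)
})

test_that("noise-free recovery of configured fractions is within 0.03 per zone", {
  cfg <- synth_config(seed = 13, zone_intensity_fractions = c(0.5, 0.3, 0.1),
                      vesicle_intensity = 20000, noise_sd = 0)
  out <- generate_image(cfg)
  res <- run_distribution_pipeline(out$image)
  rec <- as.numeric(res[1, c("perinuclear", "intermediate", "periphery")])
  expect_lt(max(abs(rec - c(0.5, 0.3, 0.1))), 0.03)
})
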