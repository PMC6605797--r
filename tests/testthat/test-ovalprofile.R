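disc_mask <- function(n, r0, c0, rad) {
  m <- matrix(0L, n, n)
  for (r in 1:n) for (c in 1:n)
    if ((r - r0)^2 + (c - c0)^2 <= rad^2) m[r, c] <- 1L
  m
}

test_that("oval fit recovers circle and ellipse axes scaled by the enlargement", {
  circ <- disc_mask(140, 70, 70, 50)
  ov <- fit_nucleus_oval(circ)
  expect_equal(ov$semi_major, 60, tolerance = 0.02)   # 50 * 1.2
  expect_equal(ov$semi_minor, 60, tolerance = 0.02)

  ell <- matrix(0L, 120, 120)
  for (r in 1:120) for (c in 1:120)
    if (((r - 60) / 20)^2 + ((c - 60) / 40)^2 <= 1) ell[r, c] <- 1L
  ov <- fit_nucleus_oval(ell)
  expect_equal(ov$semi_major, 48, tolerance = 0.02)   # 40 * 1.2
  expect_equal(ov$semi_minor, 24, tolerance = 0.02)   # 20 * 1.2

  expect_error(fit_nucleus_oval(matrix(0L, 10, 10)), "empty")
  expect_warning(fit_nucleus_oval(disc_mask(80, 20, 20, 8) +
                                    disc_mask(80, 60, 60, 12)), "largest")
})

test_that("radially symmetric images give flat profiles; wedges peak at their angle", {
  n <- 121
  img <- matrix(0, n, n)
  for (r in 1:n) for (c in 1:n) {
    d2 <- (r - 61)^2 + (c - 61)^2
    img[r, c] <- 1000 * exp(-d2 / (2 * 15^2))
  }
  oval <- list(center = c(61, 61), semi_major = 40, semi_minor = 40, theta = 0)
  prof <- radial_sum_profile(img, oval)
  expect_lt(diff(range(prof$radial_sum)) / mean(prof$radial_sum), 0.01)

  # bright wedge at 90 degrees (up in angle convention: row increases with sin)
  img2 <- matrix(0, n, n)
  for (r in 1:n) for (c in 1:n) {
    ang <- atan2(r - 61, c - 61) * 180 / pi
    d <- sqrt((r - 61)^2 + (c - 61)^2)
    if (d > 5 && d < 35 && abs(ang - 90) < 5) img2[r, c] <- 100
  }
  prof2 <- radial_sum_profile(img2, oval)
  peak_angle <- prof2$angle_deg[which.max(prof2$radial_sum)]
  expect_lt(min(abs(peak_angle - 90), 360 - abs(peak_angle - 90)), 1.5)

  # all-zero channel: zero profile, classification refuses it
  prof0 <- radial_sum_profile(matrix(0, n, n), oval)
  expect_true(all(prof0$radial_sum == 0))
  expect_error(classify_clustering(prof0), "degenerate")
})

test_that("classification is threshold-driven and scale-invariant", {
  flat <- data.frame(angle_deg = 0:359, radial_sum = rep(5, 360))
  expect_equal(classify_clustering(flat)$class, "uniform")
  expect_equal(classify_clustering(flat)$peak_ratio, 1)

  delta <- data.frame(angle_deg = 0:359, radial_sum = c(rep(0, 359), 100))
  expect_equal(classify_clustering(delta)$class, "clustered")
  expect_equal(classify_clustering(delta)$peak_ratio, 360)

  scaled <- delta
  scaled$radial_sum <- scaled$radial_sum * 1000
  expect_equal(classify_clustering(scaled)$peak_ratio,
               classify_clustering(delta)$peak_ratio)
})

test_that("synthetic clustered and cytosolic phenotypes are well separated", {
  ratios_c <- vapply(1:6, function(s) {
    classify_generated_image(generate_image(scenario_oval("clustered", s)))$peak_ratio
  }, 1)
  ratios_u <- vapply(1:6, function(s) {
    classify_generated_image(generate_image(scenario_oval("cytosolic", s + 500)))$peak_ratio
  }, 1)
  expect_true(all(ratios_c >= 2))
  expect_true(all(ratios_u < 2))
  # the two phenotypes are separable by a wide margin (ROC-like check)
  expect_gt(min(ratios_c), 2 * max(ratios_u))
})
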