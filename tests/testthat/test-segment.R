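test_that("isodata threshold matches hand-iterated intermeans fixed points", {
  # half 10s / half 200s: T = (10 + 200) / 2 = 105 at the fixed point
  m <- matrix(c(rep(10, 32), rep(200, 32)), 8, 8)
  expect_equal(threshold_isodata(m), 105)
  expect_equal(sum(m > threshold_isodata(m)), 32)

  v <- matrix(c(0, 0, 0, 255, 255), 1)
  thr <- threshold_isodata(v)
  expect_identical(which(v > thr), 4:5)

  expect_error(threshold_isodata(matrix(7, 4, 4)), "constant")
})

test_that("max entropy threshold separates a two-level image and rejects constants", {
  m <- matrix(c(rep(10, 40), rep(200, 24)), 8, 8)
  thr <- threshold_max_entropy(m)
  expect_true(thr > 10 && thr < 200)
  expect_equal(sum(m > thr), 24)
  expect_error(threshold_max_entropy(matrix(1, 3, 3)), "constant")
})

test_that("Bernsen rule follows the contrast/midgray definition", {
  # a bright pixel above local midgray in a high-contrast window
  m <- matrix(10, 9, 9)
  m[5, 5] <- 150; m[1, 1] <- 200
  mask <- threshold_bernsen(m, radius_px = 8, contrast_threshold = 15)
  expect_equal(mask[5, 5], 1L)   # contrast 190 >= 15 and 150 > 105
  # flat region: contrast 0 < 15 -> background everywhere
  expect_equal(sum(threshold_bernsen(matrix(80, 9, 9), 3, 15)), 0)
  expect_error(threshold_bernsen(matrix(1:4, 2, 2), radius_px = 5), "larger")
})

test_that("thresholds and Bernsen match brute-force oracles on random images", {
  for (s in 1:25) {
    m <- random_test_image(s, n = 16)
    expect_equal(threshold_isodata(m), oracle_isodata(m), tolerance = 1e-9)
    expect_equal(threshold_max_entropy(m), oracle_max_entropy(m),
                 tolerance = 1e-9)
    r <- sample(2:5, 1)
    ct <- sample(c(10, 15, 40), 1)
    expect_identical(threshold_bernsen(m, r, ct), oracle_bernsen(m, r, ct))
  }
})

test_that("threshold shift/offset invariances hold", {
  m <- random_test_image(99, n = 12)
  expect_identical(threshold_bernsen(m + 37, 3, 15), threshold_bernsen(m, 3, 15))
  expect_equal(threshold_isodata(m + 37), threshold_isodata(m) + 37,
               tolerance = 1e-6)
  expect_equal(threshold_max_entropy(m + 37), threshold_max_entropy(m) + 37,
               tolerance = 1e-9)
})

test_that("median filter removes isolated pixels, keeps constants, matches oracle", {
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  expect_equal(sum(median_filter(m, 1)), 0)
  flat <- matrix(3.5, 6, 6)
  expect_equal(median_filter(flat, 2), flat)
  for (s in 1:5) {
    set.seed(s)
    b <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(median_filter(b, 1), oracle_median_filter(b, 1),
                 ignore_attr = TRUE)
    g <- matrix(runif(64, 0, 100), 8, 8)
    expect_equal(median_filter(g, 2), oracle_median_filter(g, 2),
                 tolerance = 1e-12)
  }
})

test_that("distance map is exact Euclidean, zero on mask, clipped, Lipschitz", {
  m <- matrix(0L, 10, 10); m[1, 1] <- 1L
  d <- distance_map(m, clip = Inf)
  expect_equal(d[4, 5], 5)       # offset (3,4) from the mask pixel
  expect_equal(d[1, 1], 0)

  for (s in 1:10) {
    set.seed(s)
    mask <- matrix(0L, 20, 20)
    mask[sample(400, 12)] <- 1L
    d <- distance_map(mask)
    expect_equal(d, oracle_distance_map(mask), tolerance = 1e-9)
    # 1-Lipschitz in the 8-neighbour sense
    dd <- abs(d[-1, ] - d[-nrow(d), ])
    expect_true(all(dd <= sqrt(2) + 1e-9))
  }
  expect_error(distance_map(matrix(0L, 5, 5)), "empty")
})

test_that("distance map honors the 255 px clip", {
  m <- matrix(0L, 300, 300); m[1, 1] <- 1L
  expect_equal(max(distance_map(m)), 255)
  expect_gt(max(distance_map(m, clip = Inf)), 255)
})

test_that("watershed splits touching discs but never merges components", {
  disc <- function(img, r0, c0, rad) {
    for (r in 1:nrow(img)) for (c in 1:ncol(img))
      if ((r - r0)^2 + (c - c0)^2 <= rad^2) img[r, c] <- 1L
    img
  }
  two <- disc(disc(matrix(0L, 80, 120), 40, 45, 20), 40, 75, 20)
  expect_equal(max(watershed_split(two)), 2)

  one <- disc(matrix(0L, 60, 60), 30, 30, 18)
  lab <- watershed_split(one)
  expect_equal(max(lab), 1)
  expect_equal(matrix(as.integer(lab > 0), 60, 60), one)

  expect_equal(max(watershed_split(matrix(0L, 8, 8))), 0)

  for (s in 1:5) {
    set.seed(s)
    mask <- matrix(as.integer(runif(900) > 0.7), 30, 30)
    expect_gte(max(watershed_split(mask)), max(label_components(mask)))
  }
})

test_that("labeling connectivity: diagonal pixels join under 8- but not 4-connectivity", {
  m <- matrix(0L, 5, 5); m[2, 2] <- 1L; m[3, 3] <- 1L; m[5, 5] <- 1L
  expect_equal(max(label_components(m, connectivity = 8)), 2)
  expect_equal(max(label_components(m, connectivity = 4)), 3)
})
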