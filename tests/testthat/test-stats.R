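test_that("paired t test matches the textbook formula and handles degeneracies", {
  set.seed(1)
  x <- rnorm(8, 10, 2); y <- rnorm(8, 9, 2)
  res <- paired_t_test(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$statistic, t_manual)
  expect_equal(res$p_value, 2 * pt(-abs(t_manual), length(d) - 1))

  expect_warning(same <- paired_t_test(x, x), "zero")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_warning(const <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4)),
                 "constant")
  expect_equal(const$p_value, 0)

  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("one-way ANOVA F matches the direct sum-of-squares computation", {
  set.seed(2)
  vals <- c(rnorm(5, 10), rnorm(5, 12), rnorm(5, 11))
  grp <- rep(c("a", "b", "c"), each = 5)
  res <- anova_bonferroni(vals, grp)

  # direct decomposition
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ssb <- sum(5 * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  f_manual <- (ssb / 2) / (ssw / 12)
  expect_equal(res$anova$F, f_manual)
  expect_equal(res$anova$p_value, pf(f_manual, 2, 12, lower.tail = FALSE))

  # Bonferroni adjusted never below raw, ordering preserved, capped at 1
  expect_true(all(res$posthoc$p_adjusted >= res$posthoc$p_raw))
  expect_true(all(res$posthoc$p_adjusted <= 1))
  expect_equal(order(res$posthoc$p_adjusted), order(res$posthoc$p_raw))
  # adjusted = raw * number of comparisons where uncapped
  uncapped <- res$posthoc$p_adjusted < 1
  expect_equal(res$posthoc$p_adjusted[uncapped],
               res$posthoc$p_raw[uncapped] * 3)
})

test_that("identical groups give F = 0 and separated groups reach ***", {
  vals <- rep(c(1, 2, 3), times = 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_bonferroni(vals, grp)
  expect_equal(res$anova$F, 0)
  expect_equal(res$anova$p_value, 1)
  expect_equal(res$anova$tier, "ns")

  set.seed(3)
  v2 <- c(rnorm(4, 0, 0.01), rnorm(4, 10, 0.01))
  res2 <- anova_bonferroni(v2, rep(c("lo", "hi"), each = 4))
  expect_equal(res2$anova$tier, "***")
})

test_that("balanced two-way ANOVA decomposes both factors; unbalanced errors", {
  set.seed(4)
  zone <- rep(rep(c("peri", "inter", "periph"), each = 4), 2)
  trt <- rep(c("ctrl", "hist"), each = 12)
  vals <- rnorm(24, 5) + ifelse(zone == "peri" & trt == "hist", 3, 0)
  res <- anova_bonferroni(vals, zone, trt)
  expect_equal(res$test, "two_way_anova")
  expect_setequal(res$anova$term, c("group", "factor2", "group:factor2"))

  expect_error(anova_bonferroni(vals[-1], zone[-1], trt[-1]), "balanced")
})

test_that("significance tiers follow the 0.05/0.01/0.001 convention", {
  tiers <- vapply(c(0.2, 0.04, 0.009, 0.0009), wpbquant:::significance_tier, "")
  expect_equal(tiers, c("ns", "*", "**", "***"))
})
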