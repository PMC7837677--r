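test_that("trend regression is exact on a noiseless line", {
  r <- regress_trend(1:10, 2 * (1:10) + 1)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
})

test_that("trend regression matches the closed-form normal equations", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0, 0.7)
  y <- c(0.3, 1.9, 1.1, 2.8, 2.6, 3.9, 0.1)
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  r_xy <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  res <- regress_trend(x, y)
  expect_equal(res$slope, b, tolerance = 1e-10)
  expect_equal(res$intercept, a, tolerance = 1e-10)
  expect_equal(res$pearson_r, r_xy, tolerance = 1e-10)
  # slope t-test equals the correlation test
  tstat <- r_xy * sqrt((n - 2) / (1 - r_xy^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-10)
})

test_that("trend regression rejects degenerate inputs", {
  expect_error(regress_trend(c(1, 2), c(1, 2)), "at least 3")
  expect_error(regress_trend(rep(1, 5), 1:5), "zero variance")
})

test_that("study-sized synthetic data recover the release-probability slope", {
  ds <- generate_spine_dataset(n_spines = 67, trials_per_spine = 20, seed = 19)
  est <- estimate_dataset(ds)
  reg <- regress_trend(est$distance_um, est$P1)
  expect_gt(reg$conf_high, 0.0012 - 1e-9)
  expect_lt(reg$conf_low, 0.0012 + 1e-9)
  expect_lt(reg$p_value, 0.05)
})

test_that("binning pools noise away: r = 1 on a noiseless line and on average higher", {
  x <- seq(40, 350, length.out = 60)
  bp <- bin_and_pool(x, 0.18 + 0.0012 * x)
  expect_equal(bp$regression$pearson_r, 1, tolerance = 1e-9)
  expect_error(bin_and_pool(x, x, bin_width = 0), "positive")

  gains <- vapply(1:30, function(s) {
    ds <- generate_spine_dataset(67, 20, seed = 300 + s)
    est <- estimate_dataset(ds)
    raw <- regress_trend(est$distance_um, est$P1)
    bp <- bin_and_pool(est$distance_um, est$P1)
    c(bp$regression$pearson_r, raw$pearson_r)
  }, numeric(2))
  expect_gt(mean(gains[1, ]), mean(gains[2, ]))
})

test_that("binning never flips the sign of the underlying slope", {
  signs <- vapply(1:50, function(s) {
    ds <- generate_spine_dataset(67, 20, seed = 700 + s)
    est <- estimate_dataset(ds)
    sign(bin_and_pool(est$distance_um, est$P1)$regression$slope)
  }, numeric(1))
  expect_true(all(signs == 1))
})

test_that("same-branch percentage differences use the symmetric pair mean", {
  pairs <- data.frame(P1_a = c(0.3, 0.2), P1_b = c(0.3, 0.6),
                      separation_um = c(5, 20))
  pd <- pairwise_branch_difference(rbind(pairs, pairs, pairs))
  expect_equal(pd$pct_diff[1], 0)
  expect_equal(pd$pct_diff[2], 100)  # |0.2-0.6| / 0.4
  expect_error(pairwise_branch_difference(
    data.frame(P1_a = 0, P1_b = 0, separation_um = 1)), "no defined")
})

test_that("distance-autocorrelated Pr yields a positive pair-difference slope", {
  set.seed(31)
  sep <- runif(60, 2, 60)
  base <- runif(60, 0.2, 0.5)
  pairs <- data.frame(P1_a = base,
                      P1_b = pmin(0.9, base + 0.004 * sep + rnorm(60, 0, 0.02)),
                      separation_um = sep)
  expect_gt(pairwise_branch_difference(pairs)$regression$slope, 0)
})

test_that("relative branch position scales to the unit interval", {
  expect_equal(relative_branch_position(0, 100), 0)
  expect_equal(relative_branch_position(50, 100), 0.5)
  expect_equal(relative_branch_position(75, 100), 0.75)
  expect_error(relative_branch_position(10, 0), "positive")
  expect_error(relative_branch_position(110, 100), "within")
})

test_that("spine density counts a closed window", {
  expect_equal(spine_density(numeric(0), 10), 0)
  expect_equal(spine_density(1:20, 10, 10), 11)
  expect_equal(spine_density(c(5, 15), 10, 10), 2)  # both edges inclusive
  expect_error(spine_density(1:5, 3, 0), "positive")
})

test_that("paired comparisons run both tests and handle degenerate input", {
  a <- c(1.1, 2.3, 0.8, 1.9, 2.6, 1.4)
  expect_equal(compare_paired(a, a, "t"), 1)
  expect_error(compare_paired(a, a, "wilcoxon"), "zero")
  expect_error(compare_paired(a[1:3], a[1:3]), "at least 5")

  # textbook paired t on a fixed 6-point dataset vs the closed form
  b <- c(0.9, 2.0, 0.9, 1.5, 2.1, 1.0)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(compare_paired(a, b, "t"), 2 * pt(-abs(tstat), 5),
               tolerance = 1e-12)

  # power: a 1-SD shift at n = 100 is detected at p < 0.005
  hits <- vapply(1:20, function(s) {
    set.seed(900 + s)
    x <- rnorm(100); y <- x + rnorm(100, 1, 0.5)
    compare_paired(x, y, "t") < 0.005 &&
      compare_paired(x, y, "wilcoxon") < 0.005
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
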