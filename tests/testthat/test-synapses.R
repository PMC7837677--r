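test_that("release-probability profiles evaluate the printed regressions", {
  expect_equal(pr_profile(150, "trend"), 0.36)
  expect_equal(pr_profile(50, "trend"), 0.24)
  expect_equal(pr_profile(300, "trend"), 0.54)
  expect_equal(pr_profile(123, "uniform"), 0.36)
  expect_error(pr_profile(-1), "non-negative")

  expect_equal(p2_profile(195), (0.18 + 0.0012 * 195) * (3.31 - 0.0074 * 195))
  expect_equal(p2_profile(195), 0.77, tolerance = 0.01)
  expect_equal(p2_profile(50), 0.24 * 2.94, tolerance = 1e-12)
  expect_equal(p2_profile(10, "uniform"), 0.77)
  # implied paired-pulse ratio at 300 um is ~1.1
  expect_equal(p2_profile(300) / pr_profile(300), 3.31 - 0.0074 * 300,
               tolerance = 1e-12)
  expect_equal(3.31 - 0.0074 * 300, 1.09)
})

test_that("conductance profile scales linearly with its amplitude factor", {
  expect_equal(gm_profile(245, 0.002), 0.002)
  expect_equal(gm_profile(350, 1) / gm_profile(40, 1), 1.21 / 0.59)
  expect_equal(gm_profile(350, 5) / gm_profile(40, 5), 1.21 / 0.59)
  expect_error(gm_profile(100, 0), "positive")
})

test_that("synapse placement samples the requested density", {
  cp <- small_comps()
  pop <- place_synapses(cp, n = 10000, seed = 5)
  ks <- suppressWarnings(stats::ks.test(pop$x_um, "punif", 40, 350))
  expect_gt(ks$p.value, 0.01)

  pop_t <- place_synapses(cp, n = 10000, density_mode = "trend", seed = 5)
  expect_gt(mean(pop_t$x_um), 195)

  expect_equal(nrow(place_synapses(cp, n = 0)), 0)
  expect_error(place_synapses(cp, x_range = c(40, 1000)), "does not reach")
})

test_that("mean rescaling pins the population mean exactly at 0.36", {
  cp <- small_comps()
  for (s in 1:5) {
    pop <- place_synapses(cp, pr_mode = "trend", rescale_mean = TRUE,
                          seed = 100 + s)
    expect_equal(mean(pop$p1), 0.36, tolerance = 1e-12)
  }
  pop <- place_synapses(cp, pr_mode = "trend", seed = 3)
  expect_equal(cor(pop$x_um, pop$p1), 1, tolerance = 1e-12)
})

test_that("paired release sampling is Bernoulli with the marginal fields", {
  cp <- small_comps()
  pop <- place_synapses(cp, pr_mode = "uniform", seed = 1)
  pop$p1[] <- 1
  rel <- sample_paired_release(pop, seed = 2)
  expect_true(all(rel$release1))

  expect_identical(sample_paired_release(pop, seed = 9),
                   sample_paired_release(pop, seed = 9))

  pop2 <- place_synapses(cp, pr_mode = "uniform", seed = 1)
  set.seed(77)
  counts <- vapply(1:10000, function(i)
    sum(stats::runif(50) < pop2$p1), numeric(1))
  expect_lt(abs(mean(counts) - 50 * 0.36), 0.5)
})

test_that("the STP recursion honours its normalisation and calibration", {
  p <- stp_evolve(100, 0.4)
  expect_equal(p, 0.4)

  for (target in c(3.01, 2.14, 1.4, 0.72)) {
    stp <- stp_calibrate_ppr(target)
    pp <- stp_evolve(c(0, 50), 0.2, stp)
    expect_equal(pp[2] / pp[1], target, tolerance = 1e-6)
  }
  # the paired-pulse regression evaluated per synapse distance
  for (x in c(40, 150, 300)) {
    target <- 3.31 - 0.0074 * x
    stp <- stp_calibrate_ppr(target)
    pp <- stp_evolve(c(0, 50), pr_profile(x, "trend"), stp)
    expect_equal(pp[2] / pp[1], target, tolerance = 1e-6)
  }
  expect_error(stp_evolve(c(50, 0), 0.3), "sorted")
})

test_that("constant-rate trains converge to a steady release probability", {
  st <- seq(0, 450, by = 50)   # 20 Hz
  p <- stp_evolve(st, 0.36, stp_params())
  dp <- abs(diff(p))
  expect_true(all(dp[4:length(dp)] < 0.01 * p[1]))
})

test_that("vanishing time constants degenerate STP to a constant base P", {
  stp <- stp_params(U = 0.3, f_inc = 0.4, tau_facil = 1e-6, tau_rec = 1e-6)
  p <- stp_evolve(seq(0, 200, by = 10), 0.5, stp)
  expect_equal(p, rep(0.5, length(p)), tolerance = 1e-9)
})

test_that("Poisson trains have the right moments and interval law", {
  expect_length(poisson_train(0, 1000), 0)
  counts <- vapply(1:1000, function(s)
    length(poisson_train(50, 1000, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 50), 0.5)
  expect_lt(abs(var(counts) - 50), 7.5)

  isi <- diff(poisson_train(100, 60000, seed = 4))
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 0.1))
  expect_gt(ks$p.value, 0.01)
})
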