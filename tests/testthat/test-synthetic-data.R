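test_that("spine dataset encodes the distance trends in its ground truth", {
  ds <- generate_spine_dataset(n_spines = 40, trials_per_spine = 10, seed = 2)
  sp <- ds$spines
  expect_equal(sp$true_P1,
               pmin(0.99, pmax(0.01, 0.18 + 0.0012 * sp$distance_um)))
  expect_equal(sp$true_P2,
               pmin(0.99, pmax(0.01, sp$true_P1 *
                                 (3.31 - 0.0074 * sp$distance_um))))
  expect_true(all(sp$branch_origin_um <= sp$branch_length_um))
  expect_true(all(sp$distance_um >= 40 & sp$distance_um <= 350))
})

test_that("degenerate probability 1 produces all successes", {
  ds <- generate_spine_dataset(n_spines = 5, trials_per_spine = 20,
                               trend_slope = 0, trend_intercept = 1,
                               ppr_trend = c(0, 1), seed = 9)
  # clipped to 0.99: at 20 trials x 5 spines expect at most a few failures
  expect_gte(mean(ds$trials$s1), 0.95)
})

test_that("empirical success rate converges to the binomial expectation", {
  ds <- generate_spine_dataset(n_spines = 67, trials_per_spine = 20, seed = 42)
  est <- estimate_dataset(ds)
  p_true <- mean(ds$spines$true_P1)
  # SEM of the grand mean over 67 x 20 Bernoulli draws
  sem <- sqrt(mean(ds$spines$true_P1 * (1 - ds$spines$true_P1)) / (67 * 20))
  expect_lt(abs(mean(est$P1) - p_true), 3 * sem)
})

test_that("generators are bit-reproducible given a seed", {
  expect_identical(generate_spine_dataset(10, 5, seed = 7),
                   generate_spine_dataset(10, 5, seed = 7))
  expect_identical(generate_linescan_trace(c(1, 1), seed = 3),
                   generate_linescan_trace(c(1, 1), seed = 3))
  sp <- spillover_config()
  expect_identical(generate_iglu_dataset(3, spill = sp, seed = 5),
                   generate_iglu_dataset(3, spill = sp, seed = 5))
})

test_that("pulse correlation knob induces conditional dependence", {
  ds <- generate_spine_dataset(n_spines = 30, trials_per_spine = 200,
                               rho = 0.9, seed = 4)
  tr <- ds$trials
  p2_given_s1 <- mean(tr$s2[tr$s1 == 1])
  p2_given_f1 <- mean(tr$s2[tr$s1 == 0])
  expect_gt(p2_given_s1, p2_given_f1 + 0.1)
})

test_that("noiseless linescan trace has one unit-peak transient per success", {
  nm <- noise_model(baseline_sd = 1e-9, success_amplitude_mean = 10,
                    success_amplitude_cv = 0)
  tr <- generate_linescan_trace(c(1, 0), noise = nm, seed = 1)
  expect_equal(max(tr$value), 10, tolerance = 1e-3)
  # no new transient after the second stimulus: the tail decays monotonically
  post2 <- tr$time_ms > tr$stim_times[2]
  expect_true(all(diff(tr$value[post2]) <= 1e-9))
  tr00 <- generate_linescan_trace(c(0, 0), noise = nm, seed = 1)
  expect_lt(max(abs(tr00$value)), 1e-6)
})

test_that("failure trials stay below 3 SD in the response window in most seeds", {
  # Gaussian extreme-value oracle: ~21 samples in the 5-45 ms window at
  # 500 Hz give P(max < 3 SD) = pnorm(3)^21 ~ 0.97
  hits <- vapply(1:60, function(s) {
    tr <- generate_linescan_trace(c(0, 0), noise = noise_model(), seed = s)
    bl <- tr$time_ms < tr$stim_times[1]
    w <- tr$time_ms >= tr$stim_times[1] + 5 & tr$time_ms <= tr$stim_times[1] + 45
    max(tr$value[w]) - mean(tr$value[bl]) < 3 * 1
  }, logical(1))
  expect_gt(mean(hits), 0.90)
})

test_that("trial classification recovers generator ground truth round-trip", {
  nm <- noise_model(baseline_sd = 1, success_amplitude_mean = 8,
                    success_amplitude_cv = 0.1)
  outcomes <- cbind(rbinom(200, 1, 0.4), rbinom(200, 1, 0.6))
  traces <- lapply(seq_len(nrow(outcomes)), function(i)
    generate_linescan_trace(outcomes[i, ], noise = nm, seed = 1000 + i))
  got <- classify_spine_trials(traces)
  expect_gte(mean(got == outcomes), 0.99)
})

test_that("spillover arithmetic and iGluSnFR failure masking behave analytically", {
  sp <- spillover_config(synapse_density = 2.0, detection_radius = 2.0)
  expect_equal(sp$sphere_volume_um3, 4 / 3 * pi * 8)
  expect_equal(sp$n_neighbours, 67)
  # all-fail probability over 67 neighbours at Pr = 0.36 is (1-0.36)^67
  expect_lt((1 - 0.36)^sp$n_neighbours, 1e-11)
  traces <- generate_iglu_dataset(10, spill = sp, mode = "paired", seed = 8)
  first_peaks <- vapply(traces, function(tr) {
    d <- compute_dff(tr)
    w <- d$time_ms >= d$stim_times[1] & d$time_ms <= d$stim_times[1] + 45
    max(d$value[w])
  }, numeric(1))
  expect_true(all(first_peaks > 0.1))  # no observable failures
})

test_that("spillover amplitude scales linearly with releasing neighbours", {
  sp <- spillover_config()
  tr <- generate_iglu_dataset(1, spill = sp, noise_sd = 0, seed = 3)[[1]]
  amps <- tr$meta$true_amplitudes
  rel <- tr$meta$n_released
  expect_equal(amps / rel, rep(amps[1] / rel[1], length(amps)),
               tolerance = 1e-12)
})

test_that("flat PPR profile yields a null distance regression at n = 33", {
  sp <- spillover_config()
  traces <- generate_iglu_dataset(33, ppr_profile = c(0, 1.0), spill = sp,
                                  mode = "paired", seed = 12)
  res <- lapply(traces, function(tr) paired_pulse_ratio_glu(compute_dff(tr)))
  ppr <- vapply(res, function(r) r$PPR_glu, numeric(1))
  x <- vapply(traces, function(tr) tr$meta$distance_um, numeric(1))
  reg <- regress_trend(x, ppr)
  expect_gt(reg$p_value, 0.05)
})

test_that("iGluSnFR generation rejects empty neighbourhoods", {
  sp <- spillover_config(synapse_density = 0.001, detection_radius = 0.5)
  expect_equal(sp$n_neighbours, 0)
  expect_error(generate_iglu_dataset(3, spill = sp), "n_neighbours")
})

test_that("trial tables round-trip through the CSV schema", {
  ds <- generate_spine_dataset(6, 8, seed = 21)
  f <- tempfile(fileext = ".csv")
  write_trials_csv(ds, f)
  ds2 <- read_trials_csv(f)
  expect_equal(estimate_dataset(ds2)$P1, estimate_dataset(ds)$P1)
  unlink(f)
})
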