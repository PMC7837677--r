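test_that("discretisation splits cylinders and conserves frustum areas", {
  cyl <- cylinder_morph(100, 1, step = 100)
  cp <- discretise(cyl, max_seg_len = 10, spine_factor = 1)
  expect_equal(nrow(cp) - 1, 10)  # 10 segments plus the root
  expect_equal(cp$length_um[-1], rep(10, 10))

  # tapering edge: summed segment areas equal the analytic frustum area
  nodes <- data.frame(id = 1:3, type = c(1L, 4L, 4L), x = 0,
                      y = c(0, 50, 150), z = 0,
                      radius = c(8, 3, 1), parent = c(-1L, 1L, 2L))
  m <- structure(list(nodes = nodes), class = "dendrite_morphology")
  cp2 <- discretise(m, max_seg_len = 7, spine_factor = 1)
  seg2 <- cp2[cp2$x_um > 50, ]
  um <- 1e-4
  frustum <- pi * (3 + 1) * um * sqrt(((3 - 1) * um)^2 + (100 * um)^2)
  expect_equal(sum(seg2$area_cm2), frustum, tolerance = 1e-12)
  expect_error(discretise(m, max_seg_len = 0), "positive")
})

test_that("resting cell conserves voltage to the microvolt", {
  tr <- simulate_cable(small_comps(), NULL, duration = 100)
  expect_lt(max(abs(tr$vm[, 1] + 65)), 1e-3)
})

test_that("steady-state attenuation matches the analytic space constant", {
  # sealed passive cylinder, ~4 space constants long
  rm_ohm_cm2 <- 28000; ra <- 90; radius_um <- 1
  lambda_um <- sqrt((radius_um * 1e-4) * rm_ohm_cm2 / (2 * ra)) * 1e4
  cyl <- cylinder_morph(4 * lambda_um, radius_um, step = 50)
  cp <- discretise(cyl, max_seg_len = 50, spine_factor = 1)
  tr <- simulate_cable(cp, NULL, duration = 1200, stabilise_ms = 0,
                       i_clamp = data.frame(comp = 2, amp_nA = 0.01,
                                            start = 0, dur = 1200),
                       record = 1L)
  v <- tr$final_v + 65
  x <- cp$x_um
  x0 <- cp$x_um[2]
  Le <- max(x) + 25 - x0   # sealed-end position relative to the injection
  analytic <- cosh((Le - (x - x0)) / lambda_um) / cosh(Le / lambda_um)
  mid <- x > 300 & x < 3.5 * lambda_um
  rel <- (v[mid] / v[2]) / analytic[mid]
  expect_lt(max(abs(rel - 1)), 0.02)
})

test_that("halving the time step changes EPSP peaks by less than 0.5%", {
  cp <- small_comps()
  ev <- conductance_event(comp_at_distance(cp, 150), onset = 20,
                          gmax_uS = 5e-4)
  p <- vapply(c(0.05, 0.025), function(dt) {
    tr <- simulate_cable(cp, ev, duration = 100, dt = dt)
    as.numeric(epsp_amplitude(tr, 20, window = 60, ref = "rest"))
  }, numeric(1))
  expect_lt(abs(p[2] - p[1]) / p[2], 0.005)
})

test_that("spatial refinement changes the steady soma voltage by < 1%", {
  m <- small_morph()
  v <- vapply(c(10, 5), function(h) {
    cp <- discretise(m, max_seg_len = h)
    tr <- simulate_cable(cp, NULL, duration = 400,
                         i_clamp = data.frame(comp = 1, amp_nA = 0.05,
                                              start = 0, dur = 400))
    tr$final_v[1] + 65
  }, numeric(1))
  expect_lt(abs(v[2] - v[1]) / abs(v[2]), 0.01)
})

test_that("excitatory events depolarise within physical bounds", {
  cp <- small_comps()
  ev <- conductance_event(comp_at_distance(cp, 100), onset = 20,
                          gmax_uS = 1e-3)
  tr <- simulate_cable(cp, ev, duration = 120)
  amp <- epsp_amplitude(tr, 20, window = 60, ref = "rest")
  expect_gt(as.numeric(amp), 0)
  expect_lt(as.numeric(amp), 65)   # cannot exceed the driving force
  expect_false(attr(amp, "spike"))

  zero <- conductance_event(comp_at_distance(cp, 100), onset = 20,
                            gmax_uS = 0)
  tr0 <- simulate_cable(cp, zero, duration = 120)
  expect_equal(as.numeric(epsp_amplitude(tr0, 20, window = 60, ref = "rest")),
               0, tolerance = 1e-3)
})

test_that("dt must resolve the synaptic rise time", {
  cp <- small_comps()
  ev <- conductance_event(2L, onset = 10, gmax_uS = 1e-3, tau1 = 0.05)
  expect_error(simulate_cable(cp, ev, duration = 50), "tau1/4")
})

test_that("paired identical small-signal events superpose linearly", {
  cp <- small_comps()
  c100 <- comp_at_distance(cp, 100)
  single <- simulate_cable(cp, conductance_event(c100, 20, 1e-4),
                           duration = 160)
  paired <- simulate_cable(cp, rbind(conductance_event(c100, 20, 1e-4),
                                     conductance_event(c100, 70, 1e-4)),
                           duration = 160)
  # superposition oracle: the paired response equals the single response
  # plus its own 50 ms-shifted copy, to within small-signal nonlinearity
  t <- single$time_ms
  v1 <- single$vm[, 1] + 65
  shift <- round(50 / diff(t[1:2]))
  pred <- v1 + c(rep(0, shift), v1[seq_len(length(v1) - shift)])
  expect_lt(max(abs((paired$vm[, 1] + 65) - pred)), 0.02 * max(pred))
  # and the onset-subtracted second amplitude matches its prediction
  e2 <- as.numeric(epsp_amplitude(paired, 70, window = 50, ref = "onset"))
  ptr <- structure(list(time_ms = t, vm = matrix(pred - 65, ncol = 1),
                        dt = paired$dt, e_rest = -65),
                   class = "voltage_trace")
  e2_pred <- as.numeric(epsp_amplitude(ptr, 70, window = 50, ref = "onset"))
  expect_lt(abs(e2 - e2_pred) / e2_pred, 0.02)
})

test_that("passive summation is sublinear, strictly for co-located synapses", {
  cp <- small_comps()
  ca <- comp_at_distance(cp, 120)
  cb <- comp_at_distance(cp, 250)
  g <- 2e-3
  amp <- function(events) {
    tr <- simulate_cable(cp, events, duration = 100)
    as.numeric(epsp_amplitude(tr, 20, window = 60, ref = "rest"))
  }
  ea <- amp(conductance_event(ca, 20, g))
  eb <- amp(conductance_event(cb, 20, g))
  eab <- amp(rbind(conductance_event(ca, 20, g),
                   conductance_event(cb, 20, g)))
  expect_lte(eab, ea + eb + 1e-9)
  ecoloc <- amp(rbind(conductance_event(ca, 20, g),
                      conductance_event(ca, 20, g)))
  expect_lt(ecoloc, 2 * ea)
})

test_that("conductance scaling flattens the distance dependence of somatic EPSPs", {
  # long thin cylinder where attenuation dominates
  cyl <- cylinder_morph(1500, 0.25, step = 25)
  cp <- discretise(cyl, max_seg_len = 25, spine_factor = 1)
  xs <- c(40, 120, 200, 280, 350)
  amp <- function(x, g) {
    ev <- conductance_event(comp_at_distance(cp, x), 20, g)
    tr <- simulate_cable(cp, ev, duration = 100)
    as.numeric(epsp_amplitude(tr, 20, window = 60, ref = "rest"))
  }
  fixed <- vapply(xs, amp, numeric(1), g = 1e-4 * 0.9)
  scaled <- vapply(xs, function(x) amp(x, gm_profile(x, 1e-4)), numeric(1))
  expect_lt(max(scaled) / min(scaled), max(fixed) / min(fixed))
  # at fixed conductance the distal EPSP is the attenuated one
  expect_lt(fixed[length(fixed)], fixed[1])
})

test_that("spike detection counts threshold crossings robustly", {
  t <- seq(0, 100, by = 0.1)
  v <- rep(-65, length(t))
  for (tk in c(20, 40, 60)) v <- v + 100 * exp(-(t - tk)^2 / 0.5) *
      (t >= tk - 3 & t <= tk + 3)
  tr <- structure(list(time_ms = t, vm = matrix(v, ncol = 1), dt = 0.1,
                       e_rest = -65), class = "voltage_trace")
  expect_equal(length(detect_spikes(tr)), 3)
  for (th in c(-10, 0, 10))
    expect_equal(length(detect_spikes(tr, threshold_mV = th)), 3)
  sub <- structure(list(time_ms = t, vm = matrix(rep(-60, length(t)), ncol = 1),
                        dt = 0.1, e_rest = -65), class = "voltage_trace")
  expect_length(detect_spikes(sub), 0)
})

test_that("the active soma fires on strong input and stays silent at rest", {
  cp <- discretise(small_morph(), max_seg_len = 20,
                   params = cable_params(active = TRUE))
  rest <- simulate_cable(cp, NULL, duration = 200)
  expect_length(detect_spikes(rest), 0)
  ev <- conductance_event(comp_at_distance(cp, 80), onset = 20,
                          gmax_uS = 0.05)
  tr <- simulate_cable(cp, ev, duration = 100)
  sp <- detect_spikes(tr)
  expect_gte(length(sp), 1)
  expect_gt(max(tr$vm[, 1]), 0)   # overshooting spike
})
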