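test_that("GPe drift matches the closed-form right-hand side", {
  p <- gpe_params()
  # at the resting potential both quadratic factors vanish and u1 is at its
  # fixed point
  d <- gpe_drift(list(v = p$v_r, u1 = 0), p, I = 0)
  expect_equal(unname(d), c(0, 0))
  # hand-evaluated midpoint value with the default parameter set
  d <- gpe_drift(list(v = -48.5, u1 = 0), p, I = 64.0, C = 68.0)
  expect_equal(d[["dv"]], (0.943 * 4.5 * (-4.5) + 64) / 68)
  expect_error(gpe_drift(list(v = NaN, u1 = 0), p, I = 0), "non-finite")
})

test_that("STN drift gates the rebound variable below v_r_tilde", {
  p <- stn_params()
  # gate closed above the rebound threshold: u2 fixed point at zero
  d <- stn_drift(list(v = -50, u1 = 0, u2 = 0), p, I = 0)
  expect_equal(d[["du2"]], 0)
  # gate open when hyperpolarised: hand-evaluated value
  d <- stn_drift(list(v = -70, u1 = 0, u2 = 0), p, I = 0)
  expect_equal(d[["du2"]], 0.123 * 0.015 * (-70 + 60))
})

test_that("reset rules implement the after-spike map", {
  p <- gpe_params()
  s <- gpe_reset(list(v = 25.0, u1 = 10), p)
  expect_equal(s$v, -58.36)
  expect_equal(s$u1, 10.353)
  expect_error(gpe_reset(list(v = 0, u1 = 0), p), "below threshold")
  # applying the reset twice keeps incrementing u1 by d
  s2 <- gpe_reset(utils::modifyList(s, list(v = p$v_peak)), p)
  expect_equal(s2$u1, s$u1 + p$d)

  q <- stn_params()
  expect_equal(stn_threshold_gain(0, q), 0.1)
  s <- stn_reset(list(v = 15.4, u1 = 0, u2 = 0), q)
  expect_equal(s$v, -47.7)
  expect_equal(s$u1, 17.1)
  expect_equal(s$u2, -68.4)
  # threshold gain vanishes for large |u2|, so the threshold tends to v_peak
  expect_lt(stn_threshold_gain(1e6, q), 1e-5)
})

test_that("capacitance samples follow the 10%-of-mean spread", {
  set.seed(42)
  x <- sample_capacitances(68, 1e5)
  expect_equal(mean(x), 68, tolerance = 3 * 6.8 / sqrt(1e5) / 68)
  expect_equal(sd(x), 6.8, tolerance = 0.02)
  set.seed(7)
  a <- sample_capacitances(23, 100)
  set.seed(7)
  expect_identical(a, sample_capacitances(23, 100))
  expect_error(sample_capacitances(-1, 10), "positive")
})

test_that("a GPe neuron driven by its bias current fires tonically with
           near-constant steady-state intervals", {
  out <- integrate_neuron(gpe_params(), duration = 15000, noise = FALSE)
  expect_gt(length(out$spikes), 100)
  # after the adaptation transient (u1 time scale ~0.2 s) the deterministic
  # limit cycle has a constant period up to step quantisation
  isi <- diff(out$spikes[out$spikes > 8000])
  expect_gt(length(isi), 10)
  expect_lt(max(isi) - min(isi), 2 * 0.05 + 1e-9)
})

test_that("firing rate is monotone in the applied current", {
  rates <- vapply(c(0, 20, 40, 60, 80), function(I) {
    length(integrate_neuron(gpe_params(), 5000, I = I, noise = FALSE)$spikes)
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[5], rates[1])
})

test_that("subthreshold trajectories agree with a 50x-finer-step reference
           integrator", {
  for (make in list(gpe_params, stn_params)) {
    p <- make()
    # relaxation from hyperpolarised start under a subthreshold current
    out <- integrate_neuron(p, duration = 100, I = -40, dt = 0.05,
                            v0 = p$v_r - 12, noise = FALSE, record_v = TRUE)
    ref <- reference_trajectory(p, duration = 100, I = -40, dt = 0.001,
                                v0 = p$v_r - 12)
    coarse_t <- seq(0, 100, by = 0.05)
    v_ref <- approx(ref$t, ref$v, coarse_t)$y
    expect_lt(max(abs(out$v - v_ref)), 0.5)
  }
})

test_that("STN neurons rebound after release from hyperpolarisation", {
  p <- stn_params()
  dt <- 0.05
  # 500 ms tonic, 500 ms strong hyperpolarisation, 500 ms release
  I <- rep(c(0, -120, 0), each = 500 / dt)
  out <- integrate_neuron(p, duration = 1500, I = I, noise = FALSE,
                          record_v = TRUE)
  # the neuron is actually hyperpolarised below the rebound threshold
  expect_lt(min(out$v[seq(600 / dt, 1000 / dt)]), p$v_r_tilde)
  pre <- sum(out$spikes >= 400 & out$spikes < 500)
  post <- sum(out$spikes >= 1000 & out$spikes < 1100)
  expect_gt(post, pre)
})
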