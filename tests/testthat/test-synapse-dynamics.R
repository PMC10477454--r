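test_that("Euler conductance decay tracks the closed form within the Euler
           error bound", {
  expect_equal(decay_conductance(0, tau = 2, dt = 0.05), 0)
  # closed form at one time constant
  expect_equal(decay_conductance_exact(1, tau = 2, t = 2), exp(-1))
  # trajectory comparison over 10 ms at the production step size
  g <- 1
  err <- 0
  for (i in 1:(10 / 0.05)) {
    g <- decay_conductance(g, tau = 2, dt = 0.05)
    err <- max(err, abs(g - decay_conductance_exact(1, 2, i * 0.05)))
  }
  expect_lt(err, 0.005)
  expect_error(decay_conductance(-1, 2, 0.05), "non-negative")
})

test_that("ionotropic and NMDA currents follow their driving forces", {
  expect_equal(ionotropic_current(1, E = -85, v = -85), 0)
  expect_equal(ionotropic_current(1, E = -85, v = -60), -25)
  expect_equal(ionotropic_current(2, E = 0, v = -60), 120)
  expect_equal(nmda_current(0.5, 0.5, E = 0, v = -50), 0)
  expect_equal(nmda_current(1, 0.2, E = 0, v = 0), 0)
  # single-arrival effective conductance peaks at the analytic time
  t <- seq(0.01, 40, by = 0.01)
  geff <- exp(-t / 100) - exp(-t / 2)
  expect_equal(t[which.max(geff)], nmda_peak_time(2, 100), tolerance = 1e-3)
  expect_equal(nmda_peak_time(2, 100), log(50) * 2 * 100 / 98)
})

test_that("magnesium block is a sigmoid in the membrane potential", {
  expect_equal(magnesium_block(0), 1 / 1.28)
  expect_gt(magnesium_block(200), 0.999)
  v <- seq(-90, 20, by = 1)
  expect_true(all(diff(magnesium_block(v)) > 0))
  expect_true(all(magnesium_block(v) > 0 & magnesium_block(v) < 1))
})

test_that("current assembly reduces to the bias current for silent synapses", {
  g0 <- list(ampa = 0, nmda_slow = 0, nmda_fast = 0, gaba_msn = 0,
             gaba_gpe = 0)
  expect_equal(assemble_gpe_current(g0, v = -55), 64.0)
  expect_equal(assemble_stn_current(g0, v = -55), 56.1)
  # every synapse at its reversal potential also leaves only the bias
  pt <- projection_table()
  g1 <- list(ampa = 1, nmda_slow = 0, nmda_fast = 0, gaba_gpe = 2)
  expect_equal(assemble_stn_current(g1, v = pt$ctx_stn$E),
               56.1 + 2 * (pt$gpe_stn$E - pt$ctx_stn$E))
  # GABA input above its reversal potential is hyperpolarising
  gg <- utils::modifyList(g0, list(gaba_gpe = 1))
  expect_lt(assemble_stn_current(gg, v = -60), 56.1)
  # AMPA component is linear in its conductance
  ga1 <- utils::modifyList(g0, list(ampa = 1))
  ga2 <- utils::modifyList(g0, list(ampa = 2))
  expect_equal(assemble_stn_current(ga2, -60) - 56.1,
               2 * (assemble_stn_current(ga1, -60) - 56.1))
  expect_error(assemble_gpe_current(list(ampa = 0), v = -55), "missing")
})

test_that("projection table carries the reference synaptic constants", {
  pt <- projection_table(3)
  expect_equal(pt$ctx_stn$G_nmda, 0.6 * pt$ctx_stn$G)
  expect_equal(pt$stn_gpe$G_nmda, 0.36 * pt$stn_gpe$G)
  expect_equal(pt$gpe_stn$delay, pt$stn_gpe$delay)
  expect_equal(pt$msn_gpe$delay, 7.4)
  expect_equal(attr(pt, "ctx_msn_delay"), 10.5)
  expect_equal(vapply(pt, `[[`, 0, "N_out"),
               c(ctx_stn = 3, gpe_stn = 1, stn_gpe = 3, msn_gpe = 10,
                 gpe_gpe = 20))
  # scaling hook multiplies every conductance
  half <- projection_table(3, conductance_preset(3, mu_scale = 0.5))
  expect_equal(half$stn_gpe$G, pt$stn_gpe$G / 2)
})

test_that("delayed delivery arrives lambda after the presynaptic spike", {
  # one overwhelming cortical input: the STN response follows each CTX spike
  # at the synaptic delay (within a step or two of integration)
  circ <- small_circuit(seed = 3)
  circ$projections$ctx_stn$G <- 1e4   # forces a spike on arrival
  circ$projections$gpe_stn$G <- 0
  circ <- substitute_poisson(circ, "gpe", 0)
  circ$r_ctx <- 0.2   # sparse, so responses to distinct inputs rarely overlap
  rec <- run_simulation(circ, duration = 20000, seed = 2,
                        record = c("ctx", "stn"))
  ctx <- rec$spikes[rec$spikes$nucleus == "ctx", ]
  stn <- rec$spikes[rec$spikes$nucleus == "stn", ]
  lags <- vapply(ctx$time, function(t0) {
    cand <- stn$time[stn$time > t0 & stn$time < t0 + 5]
    if (length(cand) == 0) NA_real_ else min(cand) - t0
  }, 0)
  lags <- lags[!is.na(lags)]
  expect_gt(length(lags), 20)
  # modal first-response lag: the 1.0 ms delay plus the arrival and
  # threshold-crossing integration steps
  modal <- as.numeric(names(which.max(table(lags))))
  expect_gte(modal, circ$projections$ctx_stn$delay)
  expect_lte(modal, circ$projections$ctx_stn$delay + 4 * 0.05)
})
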