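test_that("identical seeds give identical spike records", {
  circ <- small_circuit(seed = 3)
  r1 <- run_simulation(circ, duration = 3000, seed = 9,
                       record = c("ctx", "msn", "stn", "gpe"))
  r2 <- run_simulation(circ, duration = 3000, seed = 9,
                       record = c("ctx", "msn", "stn", "gpe"))
  expect_identical(r1$spikes, r2$spikes)
  r3 <- run_simulation(circ, duration = 3000, seed = 10)
  expect_false(identical(r1$spikes[r1$spikes$nucleus == "stn", ],
                         r3$spikes[r3$spikes$nucleus == "stn", ]))
})

test_that("spike times are strictly inside the run and monotone per neuron", {
  circ <- small_circuit(seed = 3)
  rec <- run_simulation(circ, duration = 3000, seed = 9)
  expect_true(all(rec$spikes$time > 0 & rec$spikes$time <= 3000))
  by_neuron <- split(rec$spikes$time,
                     paste(rec$spikes$nucleus, rec$spikes$neuron))
  expect_true(all(vapply(by_neuron, function(t) !is.unsorted(t), TRUE)))
})

test_that("a noiseless unconnected population reproduces single-neuron
           dynamics", {
  circ <- small_circuit(seed = 5)
  for (nm in names(circ$projections)) {
    circ$projections[[nm]]$G <- 0
    circ$projections[[nm]]$G_nmda <- 0
  }
  rec <- run_simulation(circ, duration = 3000, seed = 2, noise = "off")
  # compare one GPe neuron against the standalone integrator with the same
  # capacitance and initial state
  set.seed(2)  # init_seed draws: stn caps, gpe caps, stn v0, gpe v0
  stn_C <- sample_capacitances(circ$stn$C_mean, circ$layouts$stn$n)
  gpe_C <- sample_capacitances(circ$gpe$C_mean, circ$layouts$gpe$n)
  stn_v0 <- runif(circ$layouts$stn$n, circ$stn$v_r, circ$stn$v_t)
  gpe_v0 <- runif(circ$layouts$gpe$n, circ$gpe$v_r, circ$gpe$v_t)
  ref <- integrate_neuron(circ$gpe, duration = 3000, C = gpe_C[1],
                          v0 = gpe_v0[1], noise = FALSE)
  got <- rec$spikes$time[rec$spikes$nucleus == "gpe" & rec$spikes$neuron == 1]
  expect_equal(got, ref$spikes)
})

test_that("Poisson-substituted nuclei fire at the requested rate,
           insensitive to synaptic input", {
  circ <- small_circuit(seed = 6)
  circ <- substitute_poisson(circ, "gpe", 30.4)
  rec <- run_simulation(circ, duration = 20000, seed = 3)
  n_gpe <- circ$layouts$gpe$n
  r <- sum(rec$spikes$nucleus == "gpe") / n_gpe / 20
  expect_lt(abs(r - 30.4), 3 * sqrt(30.4 / (n_gpe * 20)))
  # cutting all excitatory input does not change a generator's rate
  circ2 <- lesion_inputs(circ, "stn_gpe", seq_len(n_gpe))
  rec2 <- run_simulation(circ2, duration = 20000, seed = 3)
  r2 <- sum(rec2$spikes$nucleus == "gpe") / n_gpe / 20
  expect_lt(abs(r2 - r), 1.0)
})

test_that("lesioning removes exactly the targeted incoming edges", {
  circ <- build_circuit(seed = 7)
  centre3 <- order(abs(circ$layouts$stn$coords))[1:3]
  les <- lesion_inputs(circ, "ctx_stn", centre3)
  g0 <- circ$graphs$ctx_stn
  g1 <- les$graphs$ctx_stn
  expect_equal(nrow(g1), nrow(g0) - sum(g0$post %in% centre3))
  expect_false(any(g1$post %in% centre3))
  expect_identical(les$graphs$gpe_stn, circ$graphs$gpe_stn)
  expect_error(lesion_inputs(circ, "nope", 1), "unknown projection")
})

test_that("mean_rate counts spikes per neuron per second on the centre
           subset", {
  sp <- data.frame(trial = 1L, nucleus = "stn",
                   neuron = rep(1:10, each = 5),
                   time = rep(seq(100, 900, length.out = 5), 10))
  rec <- synthetic_record(sp, coords_stn = seq(-0.05, 0.05, length.out = 10))
  expect_equal(mean_rate(rec, "stn", c(0, 1000)), 5)
  expect_equal(mean_rate(rec, "stn", c(0, 1000), subset = 1:2), 5)
  empty <- synthetic_record(sp[0, ], coords_stn = seq(-0.05, 0.05,
                                                      length.out = 10))
  expect_equal(mean_rate(empty, "stn", c(0, 1000)), 0)
})

test_that("halving the integration step leaves population rates within 5%", {
  circ <- build_circuit(seed = 1)
  rates <- vapply(c(0.05, 0.025), function(dt) {
    rec <- run_simulation(circ, duration = 15000, seed = 21, dt = dt,
                          record_from = 5000)
    c(mean_rate(rec, "stn", c(5000, 15000)),
      mean_rate(rec, "gpe", c(5000, 15000)))
  }, numeric(2))
  expect_lt(abs(rates[1, 2] - rates[1, 1]) / rates[1, 1], 0.05)
  expect_lt(abs(rates[2, 2] - rates[2, 1]) / rates[2, 1], 0.05)
})

test_that("numerical blow-up is reported as an error", {
  circ <- small_circuit(seed = 8)
  circ$gpe$I_bias <- -1e310   # -Inf drive makes the quadratic drift NaN
  expect_error(run_simulation(circ, duration = 200, seed = 1), "blow-up")
})
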