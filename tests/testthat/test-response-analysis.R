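test_that("PSTH estimator is unbiased for an inhomogeneous Poisson
           surrogate", {
  # known rate profile locked to onsets: 60 Hz in bins [10, 30), 10 Hz
  # elsewhere; build spikes directly, no simulation
  set.seed(13)
  onsets <- seq(1000, by = 500, length.out = 200)
  n_neuron <- 8
  profile <- function(lag) ifelse(lag >= 10 & lag < 30, 0.06, 0.01)
  sp <- do.call(rbind, lapply(seq_len(n_neuron), function(j) {
    lag <- seq(-100, 299, by = 1) + 0.5
    hits <- lapply(onsets, function(t0) {
      keep <- runif(length(lag)) < profile(lag)
      t0 + lag[keep]
    })
    data.frame(trial = 1L, nucleus = "stn", neuron = j,
               time = unlist(hits))
  }))
  rec <- synthetic_record(sp, coords_stn = seq(-0.02, 0.02,
                                               length.out = n_neuron),
                          duration = max(onsets) + 400,
                          schedule = data.frame(time = onsets, site = 0,
                                                role = "single"))
  psth <- compute_psth(rec, "stn")
  F <- colMeans(psth$prob)
  lag <- psth$lag
  se_hi <- sqrt(0.06 * 0.94 / (200 * n_neuron))
  se_lo <- sqrt(0.01 * 0.99 / (200 * n_neuron))
  expect_lt(max(abs(F[lag >= 10 & lag < 30] - 0.06)), 3 * se_hi * 2.5)
  expect_lt(abs(mean(F[lag >= 10 & lag < 30]) - 0.06), 3 * se_hi / sqrt(20))
  expect_lt(abs(mean(F[lag < 0]) - 0.01), 3 * se_lo / sqrt(100))
  # a spike exactly at each onset gives probability 1 in the first bin
  sp1 <- data.frame(trial = 1L, nucleus = "stn", neuron = 1,
                    time = onsets + 1e-9)
  rec1 <- synthetic_record(sp1, coords_stn = 0, duration = max(onsets) + 400,
                           schedule = rec$schedule)
  p1 <- colMeans(compute_psth(rec1, "stn")$prob)
  expect_equal(unname(p1[lag == 0]), 1)
  expect_equal(sum(p1), 1)
})

test_that("window-averaged response selects neurons by coordinate", {
  sp <- data.frame(trial = 1L, nucleus = "stn", neuron = 1L, time = 150.5)
  rec <- synthetic_record(sp, coords_stn = c(0, 0.2), duration = 400,
                          schedule = data.frame(time = 150, site = 0,
                                                role = "single"))
  psth <- compute_psth(rec, "stn", window = c(-10, 10))
  F <- window_average_response(psth, s = 0, A = 0.045)
  expect_equal(sum(F), 1)          # only the spiking neuron is in the window
  F2 <- window_average_response(psth, s = 0.1, A = 0.5)
  expect_equal(sum(F2), 0.5)       # averaged with the silent neuron
  expect_error(window_average_response(psth, s = -0.4, A = 0.01),
               "no neurons")
})

test_that("modulation integrals obey their closed forms and scaling", {
  lag <- seq(-200, 249)
  F_i <- rep(0.02, length(lag))
  # identical series give exactly zero
  expect_equal(l_base(F_i, F_i, lag), 0)
  expect_equal(l_re(F_i, F_i, lag), 0)
  # constant offset delta integrates to delta^2 * T
  delta <- 0.007
  expect_equal(l_base(F_i + delta, F_i, lag), delta^2 * 190)
  expect_equal(l_re(F_i + delta, F_i, lag), delta^2 * 200)
  # quadratic scaling in the offset
  expect_equal(l_base(F_i + 2 * delta, F_i, lag),
               4 * l_base(F_i + delta, F_i, lag))
  # Riemann sum matches a trapezoid oracle on a smooth fixture
  Fs <- 0.02 + 0.01 * sin(lag / 30)
  riemann <- l_base(Fs, F_i, lag)
  sel <- lag >= -190 & lag < 0
  x <- lag[sel]
  y <- (Fs - F_i)[sel]^2
  trap <- sum((y[-1] + y[-length(y)]) / 2)   # trapezoid on the same grid
  expect_lt(abs(riemann - trap) / trap, 1e-3)
  expect_error(l_base(F_i[-1], F_i, lag), "misaligned")
})

test_that("channel width reads the floor crossing off a surface", {
  ds <- c(0.02, 0.06, 0.10, 0.15)
  surf <- structure(list(
    l_base = array(rep(c(0.5, 0.2, 0.010, 0.011), 2),
                   dim = c(1, 4, 2), dimnames = list("stn", ds, c(10, 100))),
    l_re = array(0, dim = c(1, 4, 2), dimnames = list("stn", ds, c(10, 100))),
    delta_s = ds, delta_t = c(10, 100),
    floor = list(`0.02` = matrix(c(0.009, 0.011, 0.010), 1,
                                 dimnames = list("stn", NULL)))),
    class = "modulation_surface")
  cw <- channel_width(surf, "stn")
  expect_true(cw$crossed)
  expect_equal(cw$width, 0.10)
  # statistic at the floor everywhere: zero width
  surf0 <- surf
  surf0$l_base[] <- 0.010
  expect_equal(channel_width(surf0, "stn")$width, 0)
  # never crossing: unbounded width, flagged
  surfi <- surf
  surfi$l_base[] <- 1
  cwi <- channel_width(surfi, "stn")
  expect_false(cwi$crossed)
  expect_equal(cwi$width, Inf)
})

test_that("rate distributions concentrate at the generator rate for a
           Poisson control", {
  circ <- small_circuit(seed = 4)
  circ <- substitute_poisson(circ, "gpe", 25)
  rec <- run_trials(circ, 2, seed = 6, duration = 12000)
  rd <- rate_distribution(rec, "gpe", window = c(3000, 12000))
  expect_equal(mean(rd$rate), 25, tolerance = 0.05)
  expect_lt(sd(rd$rate), 3 * sqrt(25 / 9))
})
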