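# Shared fixtures and small reference implementations used across tests.

# Fine-step reference integrator for a single neuron, written directly on the
# exported drift functions; independent of the compiled engine's code path.
reference_trajectory <- function(params, duration, I = 0, dt = 0.001,
                                 v0 = params$v_r, C = params$C_mean) {
  n <- round(duration / dt)
  is_stn <- inherits(params, "stn_params")
  state <- list(v = v0, u1 = 0, u2 = 0)
  times <- seq(0, duration, by = dt)
  v <- numeric(n + 1)
  v[1] <- state$v
  for (i in seq_len(n)) {
    d <- if (is_stn) stn_drift(state, params, I + params$I_bias, C)
         else gpe_drift(state, params, I + params$I_bias, C)
    state$v <- state$v + dt * d[["dv"]]
    state$u1 <- state$u1 + dt * d[["du1"]]
    if (is_stn) state$u2 <- state$u2 + dt * d[["du2"]]
    v[i + 1] <- state$v
  }
  list(t = times, v = v)
}

# Brute-force nearest-neighbour targets: enumerate all pairs and sort.
brute_force_nearest <- function(pre_coord, post_coords, n_out,
                                exclude = integer(0)) {
  d <- abs(post_coords - pre_coord)
  d[exclude] <- Inf
  order(d)[seq_len(n_out)]
}

# A reduced circuit small enough for fast simulation-based tests.
small_circuit <- function(seed = 1, ...) {
  build_circuit(n_ctx = 200, n_msn = 200, n_stn = 20, n_gpe = 60,
                seed = seed, ...)
}

# Synthetic spike record with known structure (no simulation).
synthetic_record <- function(spikes, coords_stn, duration = 1000,
                             n_trials = max(c(spikes$trial, 1L)),
                             schedule = data.frame(time = numeric(0),
                                                   site = numeric(0),
                                                   role = character(0))) {
  structure(list(
    spikes = spikes, schedule = schedule, duration = duration, dt = 0.05,
    coords = list(stn = coords_stn, gpe = numeric(0)),
    L = 1, seed = 0, init_seed = 0, n_trials = n_trials
  ), class = "spike_record")
}
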