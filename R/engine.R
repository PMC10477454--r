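#' Simulate a circuit
#'
#' Euler--Maruyama integration of the whole circuit at step `dt` (default
#' 0.05 ms). Spike times are the reset times of the dynamical neurons and the
#' event times of the Poisson generators. Two seed domains control the run:
#' `init_seed` draws the per-run heterogeneity (membrane capacitances and
#' initial membrane potentials, uniform between `v_r` and `v_t`), `seed`
#' drives the dynamical noise, the Poisson streams and the stimulus
#' recruitment. Trials of a peristimulus experiment share `init_seed` and
#' vary `seed`; independent initial conditions vary both.
#'
#' @param circuit an [build_circuit()] object (possibly lesioned or with
#'   Poisson-substituted nuclei).
#' @param duration simulated time in ms (without `protocol`), or `NULL` to
#'   extend until 400 ms after the last stimulus.
#' @param seed integer seed of the dynamics stream.
#' @param init_seed integer seed of the heterogeneity stream (defaults to
#'   `seed`).
#' @param protocol optional [stimulation_protocol()].
#' @param dt integration step (ms).
#' @param record nuclei to record (`"ctx"`, `"msn"`, `"stn"`, `"gpe"`).
#' @param record_from discard spikes before this time (ms).
#' @param noise `"membrane"` (default) adds `sqrt(2 theta dt) N(0,1)` to the
#'   membrane potential per step; `"literal"` uses the printed current-noise
#'   form `2 theta C xi`; `"off"` disables noise.
#' @param record_subset optional list with `stn` and/or `gpe` neuron-index
#'   vectors restricting which neurons are recorded (the dynamics are
#'   unaffected; long runs that analyse few neurons save memory and time).
#' @return Object of class `spike_record`: list with `spikes` (data frame
#'   `trial`, `nucleus`, `neuron`, `time`), `schedule`, `duration`, `dt`,
#'   `coords`, and the seeds.
#' @export
#' @examples
#' circ <- build_circuit(seed = 1)
#' rec <- run_simulation(circ, duration = 2000, seed = 1)
#' mean_rate(rec, "gpe", window = c(1000, 2000))
run_simulation <- function(circuit, duration = NULL, seed = 1,
                           init_seed = seed, protocol = NULL, dt = 0.05,
                           record = c("stn", "gpe"), record_from = 0,
                           noise = c("membrane", "literal", "off"),
                           record_subset = NULL) {
  stopifnot(inherits(circuit, "stn_gpe_circuit"), dt > 0)
  noise <- match.arg(noise)

  schedule <- if (!is.null(protocol)) build_schedule(protocol) else
    data.frame(time = numeric(0), site = numeric(0), role = character(0))
  if (is.null(duration)) {
    if (nrow(schedule) == 0)
      stop("'duration' is required when no protocol is given")
    duration <- max(schedule$time) + 400
  }
  if (nrow(schedule) > 0 && max(schedule$time) >= duration)
    stop("stimulus schedule extends beyond 'duration'")

  n_stn <- circuit$layouts$stn$n
  n_gpe <- circuit$layouts$gpe$n
  set.seed(init_seed)
  stn_C <- sample_capacitances(circuit$stn$C_mean, n_stn)
  gpe_C <- sample_capacitances(circuit$gpe$C_mean, n_gpe)
  stn_v0 <- stats::runif(n_stn, circuit$stn$v_r, circuit$stn$v_t)
  gpe_v0 <- stats::runif(n_gpe, circuit$gpe$v_r, circuit$gpe$v_t)

  pt <- circuit$projections
  theta_scale <- if (noise == "off") 0 else 1
  proj_in <- function(name) {
    p <- pt[[name]]
    csr <- graph_to_csr(circuit$graphs[[name]],
                        circuit$layouts[[p$src]]$n)
    glu <- p$receptor == "AMPA+NMDA"
    list(active = TRUE, kind = if (glu) 0L else 1L,
         G_ampa = if (glu) p$G else 0,
         G_nmda = if (glu) p$G_nmda else 0,
         G_gaba = if (glu) 0 else p$G,
         delay_steps = as.integer(round(p$delay / dt)),
         ptr = csr$ptr, tgt = csr$tgt)
  }

  net <- list(
    ctx = list(n = circuit$layouts$ctx$n, coords = circuit$layouts$ctx$coords,
               rate = circuit$r_ctx),
    msn = list(n = circuit$layouts$msn$n, rate = circuit$r_msn),
    stn = list(n = n_stn, mode = circuit$stn_mode,
               rate = if (is.na(circuit$stn_rate)) 0 else circuit$stn_rate,
               params = unclass(circuit$stn), C = stn_C, v0 = stn_v0,
               u10 = rep(0, n_stn), u20 = rep(0, n_stn),
               theta = circuit$stn$theta * theta_scale),
    gpe = list(n = n_gpe, mode = circuit$gpe_mode,
               rate = if (is.na(circuit$gpe_rate)) 0 else circuit$gpe_rate,
               params = unclass(circuit$gpe), C = gpe_C, v0 = gpe_v0,
               u10 = rep(0, n_gpe), u20 = rep(0, n_gpe),
               theta = circuit$gpe$theta * theta_scale),
    synapse = list(
      E_glu = pt$ctx_stn$E, E_gpe_stn = pt$gpe_stn$E,
      E_gaba_gpe = pt$msn_gpe$E,
      tau_ampa = pt$ctx_stn$tau, tau_nmda_rise = pt$ctx_stn$tau_rise,
      tau_nmda_decay = pt$ctx_stn$tau_decay,
      tau_gpe_stn = pt$gpe_stn$tau, tau_gaba_gpe = pt$msn_gpe$tau),
    projections = list(
      ctx_stn = proj_in("ctx_stn"), gpe_stn = proj_in("gpe_stn"),
      stn_gpe = proj_in("stn_gpe"), msn_gpe = proj_in("msn_gpe"),
      gpe_gpe = proj_in("gpe_gpe")),
    stim_time = schedule$time, stim_site = schedule$site,
    sigma_s = if (!is.null(protocol)) protocol$sigma_s else 0.05 / pi,
    ctx_to_msn = as.integer(circuit$ctx_to_msn - 1L),
    msn_kernel = msn_kernel_params(r_msn = circuit$r_msn / 1000),
    record = c("ctx", "msn", "stn", "gpe") %in% record,
    record_mask = list(stn = record_subset$stn, gpe = record_subset$gpe),
    noise = if (noise == "literal") "literal" else "membrane"
  )

  out <- simulate_circuit_cpp(net, dt, duration, record_from,
                              as.integer(seed))
  nuc <- c("ctx", "msn", "stn", "gpe")[out$pop + 1L]
  spikes <- data.frame(trial = 1L, nucleus = nuc,
                       neuron = out$neuron + 1L, time = out$time)
  structure(list(
    spikes = spikes, schedule = schedule, duration = duration, dt = dt,
    coords = lapply(circuit$layouts, `[[`, "coords"),
    L = circuit$layouts$stn$L,
    seed = seed, init_seed = init_seed, n_trials = 1L
  ), class = "spike_record")
}

#' Run repeated trials of one experiment
#'
#' Trials share the network realisation and single-neuron heterogeneity
#' (`init_seed`) but use independent noise and Poisson streams
#' (`seed + trial - 1`), matching the trial convention of peristimulus
#' averaging.
#'
#' @inheritParams run_simulation
#' @param n_trials number of trials.
#' @param ... passed to [run_simulation()].
#' @return A `spike_record` whose `spikes` carry a `trial` column.
#' @export
run_trials <- function(circuit, n_trials, seed = 1, init_seed = seed, ...) {
  recs <- lapply(seq_len(n_trials), function(k) {
    run_simulation(circuit, seed = seed + k - 1, init_seed = init_seed, ...)
  })
  out <- recs[[1]]
  sp <- lapply(seq_len(n_trials), function(k) {
    s <- recs[[k]]$spikes
    s$trial <- k
    s
  })
  out$spikes <- do.call(rbind, sp)
  out$n_trials <- n_trials
  out
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d spikes, %d trial(s), %.1f s at dt = %g ms\n",
              nrow(x$spikes), x$n_trials, x$duration / 1000, x$dt))
  if (nrow(x$schedule) > 0)
    cat(sprintf("  %d stimulus events from t = %.0f ms\n",
                nrow(x$schedule), min(x$schedule$time)))
  invisible(x)
}

#' Mean population firing rate
#'
#' Spike count divided by the number of neurons and window length. The
#' default subset is the centre third of the feature axis (coordinates in
#' `(-L/6, L/6)`), which avoids boundary effects; rates are averaged over
#' trials if the record has several.
#'
#' @param record a `spike_record`.
#' @param nucleus nucleus name.
#' @param window `c(from, to)` in ms; spikes with `from <= t < to` count.
#' @param subset neuron indices, or `NULL` for the centre subset.
#' @return Mean rate in Hz.
#' @export
mean_rate <- function(record, nucleus, window, subset = NULL) {
  stopifnot(length(window) == 2, window[2] <= record$duration)
  coords <- record$coords[[nucleus]]
  if (is.null(subset)) subset <- which(abs(coords) < record$L / 6)
  if (length(subset) == 0) stop("empty neuron subset")
  s <- record$spikes
  n <- sum(s$nucleus == nucleus & s$neuron %in% subset &
             s$time >= window[1] & s$time < window[2])
  n / (length(subset) * diff(window) / 1000) / record$n_trials
}

#' Per-neuron firing rates
#'
#' @inheritParams mean_rate
#' @return Data frame with one row per (trial, neuron): columns `trial`,
#'   `neuron`, `rate` (Hz).
#' @export
neuron_rates <- function(record, nucleus, window, subset = NULL) {
  stopifnot(length(window) == 2)
  coords <- record$coords[[nucleus]]
  if (is.null(subset)) subset <- which(abs(coords) < record$L / 6)
  s <- record$spikes
  s <- s[s$nucleus == nucleus & s$neuron %in% subset &
           s$time >= window[1] & s$time < window[2], , drop = FALSE]
  grid <- expand.grid(neuron = subset, trial = seq_len(record$n_trials))
  cnt <- table(factor(paste(s$trial, s$neuron),
                      levels = paste(grid$trial, grid$neuron)))
  data.frame(trial = grid$trial, neuron = grid$neuron,
             rate = as.vector(cnt) / (diff(window) / 1000))
}
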