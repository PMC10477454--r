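#' Exponential conductance decay
#'
#' One forward-Euler step of \eqn{\tau \dot g = -g}, the dynamics of every
#' synaptic conductance between spike arrivals: `g * (1 - dt/tau)`. The
#' closed-form solution is available via [decay_conductance_exact()] and is
#' used as the reference in integrator checks.
#'
#' @param g conductance in nS (`>= 0`).
#' @param tau decay time constant in ms (`> 0`).
#' @param dt time step in ms (`> 0`).
#' @return The decayed conductance (nS).
#' @export
decay_conductance <- function(g, tau, dt) {
  stopifnot(tau > 0, dt > 0)
  if (any(g < 0)) stop("conductance must be non-negative")
  g * (1 - dt / tau)
}

#' @rdname decay_conductance
#' @param t elapsed time in ms.
#' @export
decay_conductance_exact <- function(g, tau, t) {
  stopifnot(tau > 0)
  g * exp(-t / tau)
}

#' Ionotropic (GABA/AMPA) synaptic current
#'
#' Ohmic current \eqn{I = g (E - v)} for receptors whose rise time is
#' neglected.
#'
#' @param g conductance (nS).
#' @param E reversal potential (mV).
#' @param v membrane potential (mV).
#' @return Current in pA.
#' @export
ionotropic_current <- function(g, E, v) g * (E - v)

#' NMDA synaptic current (difference of exponentials)
#'
#' NMDA conductances rise as well as decay; both phases are carried by a slow
#' and a fast state that are incremented by the same amount on each spike
#' arrival, so the effective conductance `g_slow - g_fast` starts at zero,
#' rises with the fast time constant and decays with the slow one. The
#' voltage-dependent magnesium block [magnesium_block()] is applied by the
#' current-assembly step, not here.
#'
#' @param g_slow,g_fast slow/fast conductance states (nS).
#' @inheritParams ionotropic_current
#' @return Current in pA.
#' @export
nmda_current <- function(g_slow, g_fast, E, v) (g_slow - g_fast) * (E - v)

#' Time of peak NMDA conductance after a single arrival
#'
#' For unit increments at `t = 0`, `g_slow - g_fast` is maximal at
#' \eqn{t^* = \ln(\tau_d/\tau_r)\,\tau_r \tau_d / (\tau_d - \tau_r)}.
#'
#' @param tau_rise,tau_decay rise/decay time constants (ms).
#' @return Peak time in ms.
#' @export
nmda_peak_time <- function(tau_rise = 2, tau_decay = 100) {
  stopifnot(tau_rise < tau_decay)
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

#' Voltage-dependent magnesium block of NMDA receptors
#'
#' \deqn{B(v) = 1 / (1 + 0.28 \exp(-0.062 v)),} a sigmoid in the membrane
#' potential, strictly increasing with values in (0, 1).
#'
#' @param v membrane potential (mV).
#' @return Unblocked fraction in (0, 1).
#' @export
magnesium_block <- function(v) 1 / (1 + 0.28 * exp(-0.062 * v))

#' Assemble the total postsynaptic current of a GPe neuron
#'
#' Sum of the STN AMPA current, the magnesium-gated STN NMDA current, the
#' striatal (MSN) and pallidal (GPe) GABA currents and the bias current.
#' The stochastic membrane-noise term is added by the integrator, not here.
#'
#' @param g named list of conductance states: `ampa`, `nmda_slow`,
#'   `nmda_fast`, `gaba_msn`, `gaba_gpe` (nS).
#' @param v membrane potential (mV).
#' @param params a [gpe_params()] object (for `I_bias`).
#' @param projections a projection table, see [projection_table()].
#' @return Current in pA.
#' @export
assemble_gpe_current <- function(g, v, params = gpe_params(),
                                 projections = projection_table()) {
  need <- c("ampa", "nmda_slow", "nmda_fast", "gaba_msn", "gaba_gpe")
  if (!all(need %in% names(g)))
    stop("missing conductance component(s): ",
         paste(setdiff(need, names(g)), collapse = ", "))
  E_glu <- projections$stn_gpe$E
  ionotropic_current(g$ampa, E_glu, v) +
    magnesium_block(v) * nmda_current(g$nmda_slow, g$nmda_fast, E_glu, v) +
    ionotropic_current(g$gaba_msn, projections$msn_gpe$E, v) +
    ionotropic_current(g$gaba_gpe, projections$gpe_gpe$E, v) +
    params$I_bias
}

#' Assemble the total postsynaptic current of an STN neuron
#'
#' Sum of the cortical AMPA current, the magnesium-gated cortical NMDA
#' current, the pallidal GABA current and the bias current.
#'
#' @param g named list of conductance states: `ampa`, `nmda_slow`,
#'   `nmda_fast`, `gaba_gpe` (nS).
#' @param params a [stn_params()] object.
#' @inheritParams assemble_gpe_current
#' @return Current in pA.
#' @export
assemble_stn_current <- function(g, v, params = stn_params(),
                                 projections = projection_table()) {
  need <- c("ampa", "nmda_slow", "nmda_fast", "gaba_gpe")
  if (!all(need %in% names(g)))
    stop("missing conductance component(s): ",
         paste(setdiff(need, names(g)), collapse = ", "))
  E_glu <- projections$ctx_stn$E
  ionotropic_current(g$ampa, E_glu, v) +
    magnesium_block(v) * nmda_current(g$nmda_slow, g$nmda_fast, E_glu, v) +
    ionotropic_current(g$gaba_gpe, projections$gpe_stn$E, v) +
    params$I_bias
}
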