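#' Drift of the GPe membrane equations
#'
#' Evaluates the deterministic right-hand side of the GPe aQIF equations at a
#' given state. Used for analysis and as the reference for integrator checks;
#' the simulation engine applies the same expressions in compiled code.
#'
#' @param state list with components `v` (mV) and `u1` (pA).
#' @param params a [gpe_params()] object.
#' @param I total applied current in pA (synaptic + bias).
#' @param C membrane capacitance in pF; defaults to `params$C_mean`.
#' @return Named numeric vector `c(dv, du1)` in mV/ms and pA/ms.
#' @export
gpe_drift <- function(state, params, I, C = params$C_mean) {
  check_state(state, c("v", "u1"))
  with(params, c(
    dv = (k * (state$v - v_r) * (state$v - v_t) - state$u1 + I) / C,
    du1 = a * (b * (state$v - v_r) - state$u1)
  ))
}

#' Drift of the STN membrane equations
#'
#' As [gpe_drift()], with the additional rebound variable `u2` gated by the
#' Heaviside function \eqn{H(\tilde v_r - v)}: below the rebound threshold
#' `v_r_tilde` the variable `u2` charges towards \eqn{\tilde b (v - \tilde v_r)}.
#'
#' @param state list with components `v`, `u1`, `u2`.
#' @param params a [stn_params()] object.
#' @inheritParams gpe_drift
#' @return Named numeric vector `c(dv, du1, du2)`.
#' @export
stn_drift <- function(state, params, I, C = params$C_mean) {
  check_state(state, c("v", "u1", "u2"))
  with(params, {
    gate <- if (state$v < v_r_tilde) b_tilde * (state$v - v_r_tilde) else 0
    c(
      dv = (k * (state$v - v_r) * (state$v - v_t) -
              state$u1 - w * state$u2 + I) / C,
      du1 = a * (b * (state$v - v_r) - state$u1),
      du2 = a_tilde * (gate - state$u2)
    )
  })
}

check_state <- function(state, fields) {
  for (f in fields) {
    x <- state[[f]]
    if (is.null(x) || !is.finite(x))
      stop(sprintf("invalid neuron state: '%s' missing or non-finite", f))
  }
  invisible(state)
}

#' Reset rule for GPe neurons
#'
#' Applies the after-spike reset `v -> c`, `u1 -> u1 + d`. The caller must
#' only invoke it at threshold (`v >= v_peak`).
#'
#' @inheritParams gpe_drift
#' @return The updated state list.
#' @export
gpe_reset <- function(state, params) {
  check_state(state, c("v", "u1"))
  if (state$v < params$v_peak)
    stop("gpe_reset() called below threshold (v < v_peak)")
  state$v <- params$c
  state$u1 <- state$u1 + params$d
  state
}

#' Reset rule for STN neurons
#'
#' The STN threshold and reset depend on the rebound variable through
#' \eqn{U = (w |u_2| + 1/w)^{-1}}: a spike is registered when
#' \eqn{v \ge v_{peak} + U u_2}, and the reset is \eqn{v \to c - U u_2},
#' \eqn{u_1 \to u_1 + d}, \eqn{u_2 \to u_2 + \tilde d} (with `U` evaluated at
#' the pre-reset `u2`).
#'
#' @inheritParams stn_drift
#' @return The updated state list.
#' @export
stn_reset <- function(state, params) {
  check_state(state, c("v", "u1", "u2"))
  U <- stn_threshold_gain(state$u2, params)
  if (state$v < params$v_peak + U * state$u2)
    stop("stn_reset() called below threshold (v < v_peak + U*u2)")
  state$v <- params$c - U * state$u2
  state$u1 <- state$u1 + params$d
  state$u2 <- state$u2 + params$d_tilde
  state
}

#' @rdname stn_reset
#' @param u2 value of the rebound variable (pA).
#' @export
stn_threshold_gain <- function(u2, params) {
  1 / (params$w * abs(u2) + 1 / params$w)
}

#' Integrate a single neuron
#'
#' Euler--Maruyama integration of one aQIF neuron with an arbitrary applied
#' current trace, using the same compiled stepping code as the network engine.
#' The bias current `I_bias` from `params` is always included; `I` is the
#' extra applied current.
#'
#' @param params a [gpe_params()] or [stn_params()] object.
#' @param duration simulated time in ms.
#' @param I extra applied current (pA): a scalar or a per-step vector of
#'   length `duration/dt`.
#' @param dt integration step in ms.
#' @param C membrane capacitance (pF); defaults to the parameter-set mean.
#' @param v0,u10,u20 initial state; `v0` defaults to `v_r`.
#' @param noise logical; if `FALSE` the membrane noise term is switched off
#'   (deterministic trajectory).
#' @param seed integer seed for the noise stream.
#' @param record_v if `TRUE`, return the full membrane-potential trace.
#' @return List with `spikes` (spike times, ms), `v` (trace incl. the initial
#'   value if requested) and `state` (final `c(v, u1, u2)`).
#' @export
#' @examples
#' # tonic firing of a GPe neuron driven by its bias current alone
#' out <- integrate_neuron(gpe_params(), duration = 1000, noise = FALSE)
#' length(out$spikes)
integrate_neuron <- function(params, duration, I = 0, dt = 0.05,
                             C = params$C_mean, v0 = params$v_r,
                             u10 = 0, u20 = 0, noise = TRUE, seed = 1,
                             record_v = FALSE) {
  n_steps <- round(duration / dt)
  if (length(I) == 1) I <- rep(I, n_steps)
  if (length(I) != n_steps)
    stop("'I' must be a scalar or one value per integration step")
  is_stn <- inherits(params, "stn_params")
  theta <- if (noise) params$theta else 0
  integrate_neuron_cpp(unclass(params), is_stn, C, as.numeric(I), dt,
                       v0, u10, u20, theta, as.integer(seed), record_v)
}
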