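#' Default parameters for GPe model neurons
#'
#' Adaptive quadratic integrate-and-fire (aQIF) parameter set for prototypic
#' GPe neurons. Membrane dynamics follow
#' \deqn{C \dot v = k (v - v_r)(v - v_t) - u_1 + I, \qquad
#'       \dot u_1 = a (b (v - v_r) - u_1),}
#' with reset \eqn{v \to c}, \eqn{u_1 \to u_1 + d} when \eqn{v \ge v_{peak}}.
#' Per-neuron capacitances are drawn around `C_mean` (see
#' [sample_capacitances()]); `theta` is the membrane-noise intensity
#' (mV^2/ms) and `I_bias` the constant bias current (pA).
#'
#' @param ... named overrides of individual parameters.
#' @return An object of class `gpe_params` (a named list).
#' @export
#' @examples
#' p <- gpe_params()
#' gpe_drift(list(v = p$v_r, u1 = 0), p, I = 0) # zero drift at v_r
gpe_params <- function(...) {
  p <- list(
    C_mean = 68.0, k = 0.943, v_r = -53.0, v_t = -44.0,
    a = 0.0045, b = 3.895, v_peak = 25.0, c = -58.36, d = 0.353,
    theta = 3.0, I_bias = 64.0
  )
  p <- utils::modifyList(p, list(...))
  validate_neuron_params(p)
  structure(p, class = c("gpe_params", "neuron_params"))
}

#' Default parameters for STN model neurons
#'
#' aQIF parameter set for rebound-bursting STN neurons. In addition to the
#' GPe-type dynamics, a second recovery variable \eqn{u_2} is active below the
#' rebound threshold \eqn{\tilde v_r}:
#' \deqn{C \dot v = k (v - v_r)(v - v_t) - u_1 - w u_2 + I, \qquad
#'       \dot u_2 = \tilde a (H(\tilde v_r - v)\, \tilde b (v - \tilde v_r) - u_2).}
#' The spike threshold is \eqn{v_{peak} + U u_2} with
#' \eqn{U = (w |u_2| + 1/w)^{-1}}, and the reset is \eqn{v \to c - U u_2},
#' \eqn{u_1 \to u_1 + d}, \eqn{u_2 \to u_2 + \tilde d}. `w_tilde` is carried
#' for completeness but does not enter the dynamics.
#'
#' @inheritParams gpe_params
#' @return An object of class `stn_params`.
#' @export
stn_params <- function(...) {
  p <- list(
    C_mean = 23.0, k = 0.439, v_r = -56.2, v_t = -41.4,
    a = 0.021, b = 4.0, v_peak = 15.4, c = -47.7, d = 17.1,
    theta = 0.5, I_bias = 56.1,
    w = 0.1, w_tilde = 0.0, v_r_tilde = -60.0,
    a_tilde = 0.123, b_tilde = 0.015, d_tilde = -68.4
  )
  p <- utils::modifyList(p, list(...))
  validate_neuron_params(p)
  if (p$w <= 0) stop("'w' must be positive")
  if (p$v_r_tilde > p$v_r) stop("'v_r_tilde' must not exceed 'v_r'")
  structure(p, class = c("stn_params", "neuron_params"))
}

validate_neuron_params <- function(p) {
  stopifnot(p$C_mean > 0, p$a > 0)
  if (!(p$v_r < p$v_t && p$v_t < p$v_peak))
    stop("neuron parameters must satisfy v_r < v_t < v_peak")
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  flat <- unlist(x)
  cat(paste(sprintf("  %-9s %g", names(flat), flat), collapse = "\n"), "\n")
  invisible(x)
}

#' Sample heterogeneous membrane capacitances
#'
#' Capacitances are Gaussian with standard deviation equal to 10% of the mean.
#' Draws are truncated from below at `0.2 * mean` to exclude non-physical
#' near-zero values; at this spread the truncation probability is ~1e-15, so
#' the distribution is effectively the stated Gaussian.
#'
#' @param mean mean capacitance in pF (`> 0`).
#' @param n number of neurons.
#' @return Numeric vector of `n` capacitances (pF).
#' @export
sample_capacitances <- function(mean, n) {
  if (!is.finite(mean) || mean <= 0) stop("'mean' must be a positive number")
  if (n < 1) stop("'n' must be >= 1")
  x <- stats::rnorm(n, mean = mean, sd = 0.1 * mean)
  while (any(bad <- x < 0.2 * mean))
    x[bad] <- stats::rnorm(sum(bad), mean = mean, sd = 0.1 * mean)
  x
}
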