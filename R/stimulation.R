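#' Spatial stimulus profile
#'
#' Lorentzian recruitment probability of a cortical generator at coordinate
#' `s` for a stimulus centred at `s0`:
#' \deqn{P(s | s_0) = (1 + ((s - s_0)/\sigma_s)^2)^{-1}.}
#'
#' @param s coordinate(s) of cortical generators.
#' @param s0 stimulus centre.
#' @param sigma_s profile width (default `0.05 L / pi` with `L = 1`).
#' @return Probability in (0, 1].
#' @export
stimulus_profile <- function(s, s0 = 0, sigma_s = 0.05 / pi) {
  stopifnot(sigma_s > 0)
  1 / (1 + ((s - s0) / sigma_s)^2)
}

#' Sample the cortical generators recruited by one stimulus
#'
#' Each cortical generator is recruited independently with the profile
#' probability [stimulus_profile()]; recruited generators emit one spike at
#' stimulus onset, superposed on their baseline Poisson stream. This R-level
#' sampler mirrors the compiled engine and serves as its reference.
#'
#' @param coords cortical generator coordinates.
#' @inheritParams stimulus_profile
#' @return Integer vector of recruited generator indices.
#' @export
sample_ctx_stimulus_spikes <- function(coords, s0 = 0, sigma_s = 0.05 / pi) {
  p <- stimulus_profile(coords, s0, sigma_s)
  which(stats::runif(length(coords)) < p)
}

#' Parameters of the striatal stimulus-response kernel
#'
#' Shape constants of the evoked MSN firing-rate profile: a Gaussian burst of
#' peak rate `eta` at `mu` ms (width `sigma = mu/3`), a silent period, and a
#' linear recovery between `t_start` and `t_end` after which the rate returns
#' to the `r_msn` baseline. `delay` is the cortico-striatal latency.
#'
#' @param ... named overrides.
#' @return Named list of kernel constants (rates in 1/ms, times in ms).
#' @export
msn_kernel_params <- function(...) {
  p <- list(eta = 0.145, mu = 2.1, sigma = 2.1 / 3,
            t_start = 100, t_end = 300, delay = 10.5,
            r_msn = 0.67 / 1000, literal_ramp = FALSE)
  p <- utils::modifyList(p, list(...))
  stopifnot(p$mu > 0, p$t_start < p$t_end, p$eta > p$r_msn)
  p
}

#' Evoked striatal firing-rate kernel
#'
#' Instantaneous firing rate (1/ms) of an MSN generator at time `t` after the
#' stimulus-evoked spike of its associated cortical generator (latency
#' already removed): a Gaussian burst for `t < 2*mu`, silence for
#' `2*mu <= t < 2*mu + t_start`, a linear recovery ramp up to the baseline
#' rate on `[2*mu + t_start, 2*mu + t_end)`, and the baseline thereafter.
#' With `literal_ramp = TRUE` the ramp instead rises towards 1/ms, the
#' as-printed variant of the recovery branch.
#'
#' @param t time since the cortical stimulus spike (ms, `> 0`); vectorised.
#' @param kernel a [msn_kernel_params()] list.
#' @return Firing rate(s) in 1/ms.
#' @export
msn_rate_kernel <- function(t, kernel = msn_kernel_params()) {
  if (any(t <= 0)) stop("'t' must be positive")
  with(kernel, {
    r <- numeric(length(t))
    i1 <- t < 2 * mu
    r[i1] <- eta * exp(-(t[i1] - mu)^2 / (2 * sigma^2))
    i3 <- t >= 2 * mu + t_start & t < 2 * mu + t_end
    r[i3] <- if (literal_ramp) (t[i3] - t_start) / (t_end - t_start)
             else r_msn * (t[i3] - 2 * mu - t_start) / (t_end - t_start)
    r[t >= 2 * mu + t_end] <- r_msn
    r
  })
}

#' Per-step striatal spike probability
#'
#' Probability that an MSN generator fires between `t` and `t + h`: the
#' kernel rate times `h` if its associated cortical generator emitted a
#' stimulus-evoked spike at `t0` (most recent one governs), the baseline
#' probability `r_msn * h` otherwise.
#'
#' @param t current time (ms).
#' @param t0 time of the associated cortical stimulus spike, or `-Inf`.
#' @param kernel a [msn_kernel_params()] list.
#' @param h step size in ms (`<= 1`).
#' @return Spike probability for the step.
#' @export
msn_spike_probability <- function(t, t0 = -Inf, kernel = msn_kernel_params(),
                                  h = 0.05) {
  stopifnot(h <= 1)
  tau <- t - t0 - kernel$delay
  if (!is.finite(t0) || tau <= 0) return(kernel$r_msn * h)
  msn_rate_kernel(tau, kernel) * h
}

#' Stimulation protocol
#'
#' Describes a periodic one-site or two-site cortical stimulation schedule.
#' In two-site mode each period carries a priming pulse at coordinate
#' `-delta_s/2` followed after `delta_t` ms by a test pulse at `+delta_s/2`.
#' Stimulation starts after `warmup` ms of unstimulated settling.
#'
#' @param mode `"one-site"` or `"two-site"`.
#' @param period inter-stimulus period in ms (default 1700).
#' @param n_stimuli number of stimuli (or stimulus pairs).
#' @param s0 centre of the one-site stimulus.
#' @param delta_s,delta_t two-site separation (coordinate units) and
#'   inter-stimulus interval (ms, `0 <= delta_t < period`).
#' @param sigma_s stimulus profile width.
#' @param warmup settling time before the first stimulus (ms).
#' @return Object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(mode = c("one-site", "two-site"),
                                 period = 1700, n_stimuli = 500, s0 = 0,
                                 delta_s = 0, delta_t = 0,
                                 sigma_s = 0.05 / pi, warmup = 40000) {
  mode <- match.arg(mode)
  stopifnot(period > 0, n_stimuli >= 1, sigma_s > 0, warmup >= 0)
  if (mode == "two-site" && !(delta_t >= 0 && delta_t < period))
    stop("'delta_t' must satisfy 0 <= delta_t < period")
  structure(list(mode = mode, period = period, n_stimuli = n_stimuli,
                 s0 = s0, delta_s = delta_s, delta_t = delta_t,
                 sigma_s = sigma_s, warmup = warmup),
            class = "stimulation_protocol")
}

#' Expand a protocol into a stimulus-event schedule
#'
#' @param protocol a [stimulation_protocol()].
#' @return Data frame with columns `time` (ms), `site` (coordinate) and
#'   `role` (`"single"`, `"priming"` or `"test"`), ordered by time.
#' @export
build_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  onsets <- protocol$warmup + (seq_len(protocol$n_stimuli) - 1) * protocol$period
  if (protocol$mode == "one-site") {
    data.frame(time = onsets, site = protocol$s0, role = "single")
  } else {
    ev <- rbind(
      data.frame(time = onsets, site = -protocol$delta_s / 2, role = "priming"),
      data.frame(time = onsets + protocol$delta_t,
                 site = protocol$delta_s / 2, role = "test"))
    ev[order(ev$time, ev$site), , drop = FALSE]
  }
}

#' Onset times used for response alignment
#'
#' For one-site protocols all onsets; for two-site protocols the test-pulse
#' onsets, the reference for the priming-modulation statistics.
#'
#' @param schedule a [build_schedule()] data frame.
#' @return Numeric vector of onset times (ms).
#' @export
alignment_onsets <- function(schedule) {
  if (all(schedule$role == "single")) schedule$time
  else schedule$time[schedule$role == "test"]
}
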