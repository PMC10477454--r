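#' Peristimulus time histogram
#'
#' Per-bin spike probability of each neuron relative to the closest stimulus
#' onset, averaged over stimuli, then averaged over trials (the per-trial
#' PSTHs are averaged, not the pooled spikes). Bin width 1 ms by default.
#'
#' @param record a `spike_record`.
#' @param nucleus nucleus name.
#' @param onsets alignment onset times (ms); defaults to
#'   [alignment_onsets()] of the record's schedule.
#' @param neurons neuron indices, or `NULL` for all recorded neurons of the
#'   nucleus.
#' @param bin bin width in ms.
#' @param window lag window `c(from, to)` in ms relative to onset.
#' @return Object of class `psth`: list with `lag` (left bin edges), `prob`
#'   (matrix neurons x bins of spike probabilities per bin), `neurons`,
#'   `coords`, `n_onsets`, `n_trials`, `bin`.
#' @export
compute_psth <- function(record, nucleus, onsets = NULL, neurons = NULL,
                         bin = 1, window = c(-100, 300)) {
  if (is.null(onsets)) onsets <- alignment_onsets(record$schedule)
  if (length(onsets) == 0) stop("no stimulus onsets to align to")
  coords <- record$coords[[nucleus]]
  if (is.null(neurons)) neurons <- seq_along(coords)
  if (length(neurons) == 0) stop("empty neuron subset")
  breaks <- seq(window[1], window[2], by = bin)
  nb <- length(breaks) - 1
  onsets <- sort(onsets)
  mids <- c(-Inf, onsets[-1] - diff(onsets) / 2, Inf)

  s <- record$spikes
  s <- s[s$nucleus == nucleus & s$neuron %in% neurons, , drop = FALSE]
  lag <- s$time - onsets[findInterval(s$time, mids)]
  keep <- lag >= window[1] & lag < window[2]
  s <- s[keep, , drop = FALSE]
  lag <- lag[keep]

  prob <- matrix(0, length(neurons), nb,
                 dimnames = list(neurons, NULL))
  if (nrow(s) > 0) {
    ibin <- floor((lag - window[1]) / bin) + 1
    tab <- table(factor(s$neuron, levels = neurons), factor(ibin, levels = 1:nb))
    prob <- unclass(tab) / (length(onsets) * record$n_trials)
  }
  structure(list(lag = breaks[-length(breaks)], prob = prob,
                 neurons = neurons, coords = coords[neurons],
                 n_onsets = length(onsets), n_trials = record$n_trials,
                 bin = bin),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d neuron(s), lag [%g, %g) ms, bin %g ms, %d onsets x %d trial(s)\n",
              nrow(x$prob), min(x$lag), max(x$lag) + x$bin, x$bin,
              x$n_onsets, x$n_trials))
  invisible(x)
}

#' Distribution of single-neuron mean firing rates
#'
#' Per-neuron rates, pooled over trials, measured over a stationary window
#' (default 9 s after 31 s of settling); the default subset is the centre of
#' the feature axis. In displaced networks with few, strong STN->GPe
#' connections this distribution becomes multimodal: neurons that lose or
#' gain an input through displacement fire at distinctly lower/higher rates.
#'
#' @inheritParams mean_rate
#' @param window measurement window in ms.
#' @return Object of class `rate_histogram`: data frame of per-(trial,
#'   neuron) rates with attributes `nucleus` and `window`.
#' @export
rate_distribution <- function(record, nucleus, window = c(31000, 40000),
                              subset = NULL) {
  rates <- neuron_rates(record, nucleus, window, subset)
  structure(rates, nucleus = nucleus, window = window,
            class = c("rate_histogram", "data.frame"))
}

#' Spatio-temporal response map
#'
#' Trial-averaged instantaneous response probability `p(t, s)` as a function
#' of the lag `t` relative to stimulus onset and the feature coordinate `s`:
#' neurons are grouped into coordinate bins (0.01 L for STN/GPe, 0.001 L for
#' CTX/MSN) and their PSTHs averaged within each bin.
#'
#' @inheritParams compute_psth
#' @param coord_bin coordinate bin width; default 0.01 for STN/GPe and 0.001
#'   for CTX/MSN.
#' @return Object of class `st_map`: list with `coord` (bin centres), `lag`,
#'   `p` (matrix coord-bins x lag-bins), `nucleus`.
#' @export
spatiotemporal_map <- function(record, nucleus, onsets = NULL, bin = 1,
                               window = c(-100, 300),
                               coord_bin = if (nucleus %in% c("ctx", "msn"))
                                 0.001 else 0.01) {
  psth <- compute_psth(record, nucleus, onsets = onsets, bin = bin,
                       window = window)
  L <- record$L
  edges <- seq(-L / 2, L / 2 + coord_bin, by = coord_bin)
  grp <- findInterval(psth$coords, edges)
  p <- rowsum(psth$prob, grp) / as.vector(table(grp))
  centres <- edges[sort(unique(grp))] + coord_bin / 2
  structure(list(coord = centres, lag = psth$lag, p = p, nucleus = nucleus,
                 bin = bin, coord_bin = coord_bin),
            class = "st_map")
}

#' Coordinate-window-averaged response
#'
#' Mean PSTH of all neurons with coordinates within `A/2` of the site `s` --
#' the response function `F(t | s)` of the two-site analysis (averaging
#' width `A = 0.045 L` by default).
#'
#' @param psth a [compute_psth()] object.
#' @param s centre coordinate of the averaging window.
#' @param A window width in coordinate units.
#' @return Numeric vector over the PSTH lag axis (probability per bin).
#' @export
window_average_response <- function(psth, s, A = 0.045) {
  stopifnot(A > 0)
  sel <- abs(psth$coords - s) <= A / 2
  if (!any(sel)) stop("no neurons within the averaging window")
  colMeans(psth$prob[sel, , drop = FALSE])
}

#' Baseline modulation by a priming stimulus
#'
#' Integrated squared difference between the primed (`F_ii`) and unprimed
#' (`F_i`) response functions over the window before the test stimulus,
#' \deqn{L_{base} = \int_{t_s - T^-}^{t_s} |F_{(ii)}(t) - F_{(i)}(t)|^2 dt,}
#' evaluated as a left Riemann sum on the PSTH lag grid. It is zero iff the
#' two responses coincide on the window and grows quadratically with their
#' offset.
#'
#' @param F_ii,F_i response vectors on a common lag grid (probability per
#'   bin), e.g. from [window_average_response()].
#' @param lag lag axis (left bin edges, ms); the test onset is at lag 0.
#' @param t_s test-stimulus time on the lag axis (default 0).
#' @param T_minus window length before the test stimulus (ms).
#' @param bin bin width of the lag grid (ms).
#' @return Scalar (probability^2 x ms).
#' @export
l_base <- function(F_ii, F_i, lag, t_s = 0, T_minus = 190, bin = 1) {
  check_series(F_ii, F_i, lag)
  sel <- lag >= t_s - T_minus & lag < t_s
  if (!any(sel)) stop("lag axis does not cover the pre-test window")
  sum((F_ii[sel] - F_i[sel])^2) * bin
}

#' Evoked-response modulation by a priming stimulus
#'
#' As [l_base()], integrated over the window after the test stimulus
#' (`[t_s, t_s + T_plus)`): how much the priming stimulus changes the
#' response evoked by the test stimulus.
#'
#' @inheritParams l_base
#' @param T_plus window length after the test stimulus (ms).
#' @return Scalar (probability^2 x ms).
#' @export
l_re <- function(F_ii, F_i, lag, t_s = 0, T_plus = 200, bin = 1) {
  check_series(F_ii, F_i, lag)
  sel <- lag >= t_s & lag < t_s + T_plus
  if (!any(sel)) stop("lag axis does not cover the post-test window")
  sum((F_ii[sel] - F_i[sel])^2) * bin
}

check_series <- function(F_ii, F_i, lag) {
  if (length(F_ii) != length(lag) || length(F_i) != length(lag))
    stop("misaligned time axes: response series and lag grid differ in length")
  invisible(NULL)
}

#' Two-site priming/test modulation surface
#'
#' For every combination of site separation `delta_s` and inter-stimulus
#' interval `delta_t`, simulates (i) one-site stimulation of the test site
#' at `+delta_s/2` and (ii) two-site stimulation (priming at `-delta_s/2`,
#' test `delta_t` ms later), aligns responses to the test onsets, averages
#' them over the coordinate window of width `A` around the test site and
#' evaluates [l_base()] and [l_re()] for STN and GPe. The one-site reference
#' is shared across the `delta_t` column of each `delta_s`. Optionally a
#' zero-priming noise floor is estimated from additional independent
#' one-site runs (`n_floor` pairs per `delta_s`).
#'
#' @param circuit a circuit object.
#' @param delta_s,delta_t grids of separations and intervals (`delta_t > 0`).
#' @param n_stimuli stimulus pairs per run.
#' @param n_trials trials per run.
#' @param seed base seed; every run derives its own stream from it.
#' @param warmup settling time before stimulation (ms).
#' @param A coordinate averaging width.
#' @param T_minus,T_plus integration windows (ms).
#' @param n_floor independent one-site run pairs for the noise floor
#'   (0 disables).
#' @param period inter-stimulus period in ms. The default is the reference
#'   1.7 s; any value exceeding the ~600 ms evoked-response recovery leaves
#'   the statistics unchanged while shortening long sweeps.
#' @param nuclei which nuclei to analyse.
#' @return Object of class `modulation_surface`: list of arrays
#'   `l_base[nucleus, delta_s, delta_t]`, `l_re[...]`, the grids, and
#'   optional `floor` samples per nucleus and `delta_s`.
#' @export
modulation_surface <- function(circuit, delta_s, delta_t, n_stimuli = 20,
                               n_trials = 1, seed = 1, warmup = 10000,
                               A = 0.045, T_minus = 190, T_plus = 200,
                               n_floor = 0, nuclei = c("stn", "gpe"),
                               period = 1700) {
  stopifnot(all(delta_t > 0))
  window <- c(-max(T_minus, max(delta_t) + 50), T_plus + 50)
  run_F <- function(mode, ds, dtt, run_seed) {
    prot <- stimulation_protocol(mode, period = period,
                                 n_stimuli = n_stimuli,
                                 s0 = ds / 2, delta_s = ds, delta_t = dtt,
                                 warmup = warmup)
    # only the neurons inside the averaging window enter F; restricting the
    # recording to them leaves the dynamics untouched and keeps long sweeps
    # affordable
    sel <- lapply(stats::setNames(nuclei, nuclei), function(nuc)
      which(abs(circuit$layouts[[nuc]]$coords - ds / 2) <= A / 2))
    rec <- run_trials(circuit, n_trials, seed = run_seed,
                      protocol = prot, record = nuclei,
                      record_from = warmup - 2 * T_minus,
                      record_subset = sel)
    lapply(stats::setNames(nuclei, nuclei), function(nuc) {
      psth <- compute_psth(rec, nuc, neurons = sel[[nuc]], window = window)
      window_average_response(psth, s = ds / 2, A = A)
    })
  }
  lag <- seq(window[1], window[2] - 1)
  dims <- c(length(nuclei), length(delta_s), length(delta_t))
  Lb <- array(NA_real_, dims, dimnames = list(nuclei, delta_s, delta_t))
  Lr <- Lb
  floor_samples <- list()
  for (i in seq_along(delta_s)) {
    ds <- delta_s[i]
    F_i <- run_F("one-site", ds, 0, seed + 1000 * i)
    for (j in seq_along(delta_t)) {
      F_ii <- run_F("two-site", ds, delta_t[j], seed + 1000 * i + 10 * j)
      for (nuc in nuclei) {
        Lb[nuc, i, j] <- l_base(F_ii[[nuc]], F_i[[nuc]], lag, T_minus = T_minus)
        Lr[nuc, i, j] <- l_re(F_ii[[nuc]], F_i[[nuc]], lag, T_plus = T_plus)
      }
    }
    if (n_floor > 0) {
      fl <- vapply(seq_len(n_floor), function(k) {
        F_a <- run_F("one-site", ds, 0, seed + 1000 * i + 500 + k)
        vapply(nuclei, function(nuc)
          l_base(F_a[[nuc]], F_i[[nuc]], lag, T_minus = T_minus), 0)
      }, numeric(length(nuclei)))
      floor_samples[[as.character(ds)]] <-
        matrix(fl, nrow = length(nuclei), dimnames = list(nuclei, NULL))
    }
  }
  structure(list(l_base = Lb, l_re = Lr, delta_s = delta_s,
                 delta_t = delta_t, floor = floor_samples,
                 A = A, T_minus = T_minus, T_plus = T_plus,
                 n_stimuli = n_stimuli, n_trials = n_trials),
            class = "modulation_surface")
}

#' Functional channel width from a modulation surface
#'
#' Reads the width of a functional channel off a modulation surface: at a
#' saturated (large) inter-stimulus interval, the smallest site separation
#' `delta_s` at which the chosen statistic drops to the noise floor -- the
#' separation beyond which the priming stimulus no longer measurably
#' modulates the test site. The floor is `mean + margin * sd` of the
#' zero-priming surrogate statistics; if the statistic starts at or below
#' the floor the width is 0, and if it never crosses within the grid the
#' width is unbounded (`Inf`) and flagged.
#'
#' @param surface a [modulation_surface()].
#' @param nucleus `"stn"` or `"gpe"`.
#' @param stat `"l_base"` (default) or `"l_re"`.
#' @param dt_index which `delta_t` column to use (default: the largest).
#' @param floor noise-floor samples (numeric vector); defaults to the
#'   surface's stored zero-priming samples for the nucleus.
#' @param margin floor margin in standard deviations (default 3).
#' @return List with `width`, `floor`, `crossed` (logical) and the profile.
#' @export
channel_width <- function(surface, nucleus, stat = c("l_base", "l_re"),
                          dt_index = length(surface$delta_t), floor = NULL,
                          margin = 3) {
  stat <- match.arg(stat)
  prof <- surface[[stat]][nucleus, , dt_index]
  if (is.null(floor)) {
    if (length(surface$floor) == 0)
      stop("no zero-priming floor samples stored; supply 'floor'")
    floor <- unlist(lapply(surface$floor, function(m) m[nucleus, ]))
  }
  thr <- mean(floor) + margin * stats::sd(c(floor, recursive = TRUE))
  if (is.na(thr)) thr <- mean(floor)
  below <- prof <= thr
  if (below[1]) {
    width <- 0
    crossed <- TRUE
  } else if (any(below)) {
    width <- surface$delta_s[which(below)[1]]
    crossed <- TRUE
  } else {
    width <- Inf
    crossed <- FALSE
  }
  list(width = width, floor = thr, crossed = crossed,
       profile = prof, delta_s = surface$delta_s)
}
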