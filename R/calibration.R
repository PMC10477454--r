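#' Combined rate mismatch of the intact circuit
#'
#' The objective of the final calibration stage: deviations of the STN and
#' GPe mean rates from their targets (11.8 and 30.4 Hz), each normalised by
#' the experimentally observed standard deviation of single-neuron baseline
#' rates (9.1 and 11.4 Hz):
#' \deqn{\Delta R = |r_{STN} - 11.8| / 9.1 + |r_{GPe} - 30.4| / 11.4.}
#' Non-negative, zero only at the exact targets.
#'
#' @param r_stn,r_gpe mean firing rates in Hz.
#' @return Dimensionless mismatch.
#' @export
delta_r <- function(r_stn, r_gpe) {
  abs(r_stn - rate_targets$stn) / rate_targets$sd_stn +
    abs(r_gpe - rate_targets$gpe) / rate_targets$sd_gpe
}

# target rates (Hz) from the in-vivo recordings the model is fitted to:
# GPe-lesioned STN 20.7; intact STN 11.8 +- 9.1; intact GPe 30.4 +- 11.4;
# GABA-blocked GPe +55% => 1.55 * 30.4
rate_targets <- list(
  stn_isolated = 20.7, stn = 11.8, gpe = 30.4,
  sd_stn = 9.1, sd_gpe = 11.4,
  gpe_disinhibited = 1.55 * 30.4
)

#' Reduced circuits of the calibration pipeline
#'
#' Builds the network reduction each calibration stage is run on:
#' \describe{
#'   \item{stage 1}{isolated CTX->STN circuit (GPe input removed); free
#'     parameter `G^CTX,STN`, target 20.7 Hz (GPe-lesioned rats).}
#'   \item{stage 2}{GPe replaced by 30.4 Hz Poisson generators feeding the
#'     STN; free `G^GPe,STN`, target 11.8 Hz.}
#'   \item{stage 3}{STN replaced by 11.8 Hz Poisson generators driving the
#'     GPe, all GABAergic input to GPe removed; free `G^STN,GPe`, target
#'     1.55 x 30.4 = 47.12 Hz (GABA-antagonist disinhibition).}
#'   \item{stage 4}{intact circuit; free (`G^MSN,GPe`, `G^GPe,GPe`),
#'     objective [delta_r()].}
#' }
#'
#' @param stage 1-4.
#' @param n_stn_gpe STN->GPe out-degree (3 or 30).
#' @param conductances starting conductance set.
#' @param seed structure seed passed to [build_circuit()].
#' @return A circuit object.
#' @export
stage_circuit <- function(stage, n_stn_gpe = 3,
                          conductances = conductance_preset(n_stn_gpe),
                          seed = 1) {
  circ <- build_circuit(n_stn_gpe = n_stn_gpe, conductances = conductances,
                        seed = seed)
  if (stage == 1) {
    circ$projections$gpe_stn$G <- 0
    circ <- substitute_poisson(circ, "gpe", 0)
  } else if (stage == 2) {
    circ <- substitute_poisson(circ, "gpe", rate_targets$gpe)
  } else if (stage == 3) {
    circ$projections$msn_gpe$G <- 0
    circ$projections$gpe_gpe$G <- 0
    circ <- substitute_poisson(circ, "stn", rate_targets$stn)
  } else if (stage != 4) {
    stop("'stage' must be 1, 2, 3 or 4")
  }
  circ
}

stage_rate <- function(circ, seed, sim_ms, nucleus) {
  rec <- run_simulation(circ, duration = sim_ms, seed = seed,
                        init_seed = seed,
                        record = nucleus, record_from = 0.75 * sim_ms - 1)
  mean_rate(rec, nucleus, c(0.75 * sim_ms, sim_ms))
}

#' Run one conductance-calibration stage
#'
#' Fits the stage's free conductance(s) by minimising the absolute rate
#' mismatch (stages 1-3) or [delta_r()] (stage 4) with a derivative-free
#' Nelder--Mead simplex. The search runs in log-conductance space, which
#' keeps conductances positive. The rate estimate for each candidate is the
#' mean over `n_init` independent initial conditions (heterogeneity +
#' noise), each simulated for `sim_s` seconds with rates measured over the
#' final quarter of the run on the centre subset.
#'
#' @param stage 1-4.
#' @param n_stn_gpe STN->GPe out-degree.
#' @param G_init starting value(s) of the free conductance(s) (nS); defaults
#'   to the fitted preset values.
#' @param n_init initial conditions averaged per evaluation (the reference
#'   protocol uses 12; 4 by default).
#' @param sim_s simulated seconds per evaluation (reference protocol: 40).
#' @param seed base seed.
#' @param tol convergence tolerance on the objective (Hz for stages 1-3).
#' @param maxit simplex iteration cap; on hitting it the best-so-far value
#'   is reported with `converged = FALSE`.
#' @return Object of class `calibration_result`: list with `stage`,
#'   `conductance` (fitted, nS), `achieved` (rate(s) at the optimum, Hz),
#'   `target`, `trace` (evaluation log) and `converged`.
#' @export
run_stage <- function(stage, n_stn_gpe = 3, G_init = NULL, n_init = 4,
                      sim_s = 40, seed = 1, tol = 0.1, maxit = 60) {
  preset <- conductance_preset(n_stn_gpe)
  free <- switch(stage, "ctx_stn", "gpe_stn", "stn_gpe",
                 c("msn_gpe", "gpe_gpe"))
  if (is.null(G_init)) G_init <- unlist(preset[free])
  target <- switch(stage, rate_targets$stn_isolated, rate_targets$stn,
                   rate_targets$gpe_disinhibited,
                   c(rate_targets$stn, rate_targets$gpe))
  trace <- list()

  rates_at <- function(G) {
    cond <- utils::modifyList(preset, as.list(stats::setNames(G, free)))
    nucleus <- if (stage == 3) "gpe" else if (stage == 4) c("stn", "gpe")
               else "stn"
    r <- vapply(seq_len(n_init), function(k) {
      circ <- stage_circuit(stage, n_stn_gpe, cond, seed = seed + k)
      vapply(nucleus, function(nuc)
        stage_rate(circ, seed = seed + 100 * k, sim_ms = sim_s * 1000,
                   nucleus = nuc), 0)
    }, numeric(if (stage == 4) 2 else 1))
    if (stage == 4) rowMeans(matrix(r, nrow = 2)) else mean(r)
  }
  objective <- function(logG) {
    r <- rates_at(exp(logG))
    val <- if (stage == 4) delta_r(r[1], r[2]) else abs(r - target)
    trace[[length(trace) + 1]] <<- list(G = exp(logG), rates = r, value = val)
    val
  }

  ctrl <- list(maxit = maxit, reltol = tol / max(abs(target)), warn.1d.NelderMead = FALSE)
  opt <- suppressWarnings(
    stats::optim(log(G_init), objective, method = "Nelder-Mead",
                 control = ctrl))
  best <- exp(opt$par)
  achieved <- rates_at(best)
  structure(list(stage = stage, n_stn_gpe = n_stn_gpe,
                 conductance = stats::setNames(best, free),
                 achieved = achieved, target = target,
                 value = opt$value, converged = opt$convergence == 0,
                 trace = trace),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> stage %d (N^STN,GPe = %d)%s\n",
              x$stage, x$n_stn_gpe,
              if (x$converged) "" else " [iteration cap reached]"))
  cat("  fitted G (nS):",
      paste(sprintf("%s = %.4g", names(x$conductance), x$conductance),
            collapse = ", "), "\n")
  cat("  achieved rate(s):", paste(sprintf("%.2f", x$achieved), collapse = ", "),
      "Hz; target:", paste(x$target, collapse = ", "), "Hz\n")
  invisible(x)
}

#' Forward-check published conductances
#'
#' Simulates each calibration stage's reduced circuit at a given (e.g. the
#' published) conductance set without re-optimising, and reports achieved
#' mean rates with Monte-Carlo standard errors over independent initial
#' conditions.
#'
#' @param n_stn_gpe STN->GPe out-degree (3 or 30).
#' @param conductances conductance set to check.
#' @param stages which stages to check.
#' @param n_seeds independent initial conditions per stage (>= 3).
#' @param sim_s simulated seconds per run; rates over the final quarter.
#' @param seed base seed.
#' @return Data frame with columns `stage`, `nucleus`, `rate`, `se`,
#'   `target`, `n`.
#' @export
verify_conductances <- function(n_stn_gpe = 3,
                                conductances = conductance_preset(n_stn_gpe),
                                stages = 1:4, n_seeds = 3, sim_s = 40,
                                seed = 1) {
  rows <- list()
  for (stage in stages) {
    nuclei <- if (stage == 3) "gpe" else if (stage == 4) c("stn", "gpe")
              else "stn"
    target <- switch(stage,
                     rate_targets$stn_isolated, rate_targets$stn,
                     rate_targets$gpe_disinhibited,
                     c(rate_targets$stn, rate_targets$gpe))
    r <- vapply(seq_len(n_seeds), function(k) {
      circ <- stage_circuit(stage, n_stn_gpe, conductances,
                            seed = seed + 31 * stage + k)
      vapply(nuclei, function(nuc)
        stage_rate(circ, seed = seed + 1000 * stage + 17 * k,
                   sim_ms = sim_s * 1000, nucleus = nuc), 0)
    }, numeric(length(nuclei)))
    r <- matrix(r, nrow = length(nuclei))
    for (i in seq_along(nuclei)) {
      rows[[length(rows) + 1]] <- data.frame(
        stage = stage, nucleus = nuclei[i],
        rate = mean(r[i, ]), se = stats::sd(r[i, ]) / sqrt(n_seeds),
        target = target[i], n = n_seeds)
    }
  }
  do.call(rbind, rows)
}
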