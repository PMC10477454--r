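#' Fitted peak-conductance presets
#'
#' Peak synaptic conductances obtained from the four-stage firing-rate
#' calibration (see [run_stage()]), for focused (`n_stn_gpe = 3`) or diffuse
#' (`n_stn_gpe = 30`) STN-to-GPe projections. The striato-pallidal value for
#' `n_stn_gpe = 3` exists in two published variants; `msn_gpe = "text"`
#' (5.54 nS, the value co-reported with the achieved firing rates) is the
#' default, `"table3"` selects 5.81 nS.
#'
#' @param n_stn_gpe number of outgoing STN->GPe connections per STN neuron,
#'   3 or 30.
#' @param msn_gpe `"text"` or `"table3"` (only distinct for `n_stn_gpe = 3`).
#' @param mu_scale overall multiplier applied to every conductance
#'   (default 1).
#' @return Named list of peak AMPA/GABA conductances in nS: `ctx_stn`,
#'   `gpe_stn`, `stn_gpe`, `msn_gpe`, `gpe_gpe`. NMDA peaks are derived from
#'   the AMPA values by fixed ratios in [projection_table()].
#' @export
conductance_preset <- function(n_stn_gpe = 3, msn_gpe = c("text", "table3"),
                               mu_scale = 1) {
  msn_gpe <- match.arg(msn_gpe)
  g <- if (n_stn_gpe == 3) {
    list(ctx_stn = 0.125, gpe_stn = 1.11, stn_gpe = 15.8,
         msn_gpe = if (msn_gpe == "text") 5.54 else 5.81, gpe_gpe = 0.44)
  } else if (n_stn_gpe == 30) {
    list(ctx_stn = 0.125, gpe_stn = 1.11, stn_gpe = 1.5,
         msn_gpe = 12.0, gpe_gpe = 0.21)
  } else {
    stop("'n_stn_gpe' must be 3 or 30")
  }
  lapply(g, function(x) x * mu_scale)
}

#' Synaptic projection table
#'
#' Per-pathway synaptic constants: receptor composition, decay (and, for
#' NMDA, rise) time constants, transmission delays, reversal potentials,
#' out-degrees and peak conductances. NMDA peak increments are fixed ratios
#' of the corresponding AMPA peak: 0.6 for CTX->STN and 0.36 for STN->GPe.
#' The GPe->STN delay equals the STN->GPe AMPA delay (1.0 ms), and the
#' CTX->MSN latency (10.5 ms) enters the striatal response kernel rather
#' than a conductance.
#'
#' @param n_stn_gpe out-degree of the STN->GPe projection (3 or 30).
#' @param conductances named list as returned by [conductance_preset()].
#' @return Named list of projections (`ctx_stn`, `gpe_stn`, `stn_gpe`,
#'   `msn_gpe`, `gpe_gpe`), each with fields `src`, `dst`, `receptor`, `tau`
#'   (+ `tau_rise`/`tau_decay` for NMDA), `delay`, `E`, `N_out`, `G`
#'   (AMPA/GABA peak) and `G_nmda`; plus `ctx_msn_delay`.
#' @export
projection_table <- function(n_stn_gpe = 3,
                             conductances = conductance_preset(n_stn_gpe)) {
  stopifnot(n_stn_gpe >= 1)
  pt <- list(
    ctx_stn = list(src = "ctx", dst = "stn", receptor = "AMPA+NMDA",
                   tau = 2, tau_rise = 2, tau_decay = 100,
                   delay = 1.0, E = 0, N_out = 3,
                   G = conductances$ctx_stn,
                   G_nmda = 0.6 * conductances$ctx_stn),
    gpe_stn = list(src = "gpe", dst = "stn", receptor = "GABA",
                   tau = 8, delay = 1.0, E = -84, N_out = 1,
                   G = conductances$gpe_stn, G_nmda = 0),
    stn_gpe = list(src = "stn", dst = "gpe", receptor = "AMPA+NMDA",
                   tau = 2, tau_rise = 2, tau_decay = 100,
                   delay = 1.0, E = 0, N_out = n_stn_gpe,
                   G = conductances$stn_gpe,
                   G_nmda = 0.36 * conductances$stn_gpe),
    msn_gpe = list(src = "msn", dst = "gpe", receptor = "GABA",
                   tau = 5, delay = 7.4, E = -85, N_out = 10,
                   G = conductances$msn_gpe, G_nmda = 0),
    gpe_gpe = list(src = "gpe", dst = "gpe", receptor = "GABA",
                   tau = 5, delay = 5.0, E = -85, N_out = 20,
                   G = conductances$gpe_gpe, G_nmda = 0)
  )
  for (nm in names(pt)) {
    p <- pt[[nm]]
    stopifnot(p$tau > 0, p$delay >= 0, p$G >= 0, p$G_nmda >= 0)
    if (!is.null(p$tau_rise)) stopifnot(p$tau_rise < p$tau_decay)
  }
  attr(pt, "ctx_msn_delay") <- 10.5
  pt
}
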