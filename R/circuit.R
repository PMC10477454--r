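#' Build an STN-GPe circuit
#'
#' Assembles the full model circuit: population layouts on the feature axis
#' (1000 CTX and 1000 MSN Poisson generators, 100 STN and 300 GPe dynamical
#' neurons by default), the five synaptic projections wired as an intact
#' (N), displaced (D) or skipping (S) topographic network, the neuron
#' parameter sets and the baseline generator rates (CTX 4 Hz, MSN 0.67 Hz).
#' The construction is a pure function of `seed`: identical seeds give
#' identical layouts and edge lists.
#'
#' @param n_stn_gpe out-degree of the STN->GPe projection (3 or 30).
#' @param network `"N"`, `"D"` or `"S"`.
#' @param conductances peak conductances, see [conductance_preset()].
#' @param seed integer seed for the structure stream (layout offsets and
#'   D-network edge selection).
#' @param P,d D-network displacement fraction and shift.
#' @param n_ctx,n_msn,n_stn,n_gpe population sizes.
#' @param r_ctx,r_msn baseline Poisson rates in Hz.
#' @param gpe,stn neuron parameter sets.
#' @return Object of class `stn_gpe_circuit`.
#' @export
#' @examples
#' circ <- build_circuit(n_stn_gpe = 3, seed = 1)
#' circ
build_circuit <- function(n_stn_gpe = 3, network = c("N", "D", "S"),
                          conductances = conductance_preset(n_stn_gpe),
                          seed = 1, P = 0.1, d = 0.15,
                          n_ctx = 1000, n_msn = 1000, n_stn = 100,
                          n_gpe = 300, r_ctx = 4, r_msn = 0.67,
                          gpe = gpe_params(), stn = stn_params()) {
  network <- match.arg(network)
  set.seed(seed)
  L <- 1
  layouts <- list(
    ctx = place_neurons(n_ctx, L, 1e-4 * L),
    msn = place_neurons(n_msn, L, 1e-4 * L),
    stn = place_neurons(n_stn, L, 1e-3 * L),
    gpe = place_neurons(n_gpe, L, 1e-3 * L)
  )
  projections <- projection_table(n_stn_gpe, conductances)

  build_one <- function(proj) {
    pre <- layouts[[proj$src]]
    post <- layouts[[proj$dst]]
    self <- identical(proj$src, proj$dst)
    g <- switch(network,
      N = build_n_network(pre, post, proj$N_out, exclude_self = self),
      D = build_d_network(build_n_network(pre, post, proj$N_out,
                                          exclude_self = self),
                          pre, post, P = P, d = d, exclude_self = self),
      S = build_s_network(pre, post, proj$N_out, exclude_self = self))
    g
  }
  graphs <- lapply(projections, build_one)

  # each cortical generator drives the striatal generator closest to it
  ctx_to_msn <- vapply(layouts$ctx$coords, function(s) {
    which.min(abs(layouts$msn$coords - s))
  }, 0L)

  structure(list(
    layouts = layouts, graphs = graphs, projections = projections,
    conductances = conductances, network = network, n_stn_gpe = n_stn_gpe,
    P = if (network == "D") P else 0, d = if (network == "D") d else 0,
    r_ctx = r_ctx, r_msn = r_msn,
    gpe = gpe, stn = stn,
    stn_mode = "dynamical", gpe_mode = "dynamical",
    stn_rate = NA_real_, gpe_rate = NA_real_,
    ctx_to_msn = ctx_to_msn, seed = seed
  ), class = "stn_gpe_circuit")
}

#' @export
print.stn_gpe_circuit <- function(x, ...) {
  cat(sprintf(
    "<stn_gpe_circuit> %s-network, N^STN,GPe = %d (structure seed %d)\n",
    x$network, x$n_stn_gpe, x$seed))
  cat(sprintf("  populations: CTX %d, MSN %d, STN %d (%s), GPe %d (%s)\n",
              x$layouts$ctx$n, x$layouts$msn$n, x$layouts$stn$n, x$stn_mode,
              x$layouts$gpe$n, x$gpe_mode))
  g <- x$conductances
  cat(sprintf(
    "  G (nS): ctx->stn %.3g, gpe->stn %.3g, stn->gpe %.3g, msn->gpe %.3g, gpe->gpe %.3g\n",
    g$ctx_stn, g$gpe_stn, g$stn_gpe, g$msn_gpe, g$gpe_gpe))
  invisible(x)
}

#' Cut incoming connections of selected neurons
#'
#' Removes every edge of one projection that targets the given postsynaptic
#' neurons; everything else is untouched. This reproduces local antagonist-
#' injection experiments (e.g. blocking all cortical input to the centre
#' three STN neurons).
#'
#' @param circuit an [build_circuit()] object.
#' @param projection one of `"ctx_stn"`, `"gpe_stn"`, `"stn_gpe"`,
#'   `"msn_gpe"`, `"gpe_gpe"`.
#' @param targets postsynaptic neuron indices (1-based).
#' @return The lesioned circuit.
#' @export
lesion_inputs <- function(circuit, projection, targets) {
  if (!projection %in% names(circuit$graphs))
    stop("unknown projection: ", projection)
  g <- circuit$graphs[[projection]]
  n_post <- circuit$layouts[[circuit$projections[[projection]]$dst]]$n
  if (any(targets < 1 | targets > n_post))
    stop("lesion target indices out of range")
  circuit$graphs[[projection]] <- g[!(g$post %in% targets), , drop = FALSE]
  circuit
}

#' Replace a dynamical nucleus by Poisson generators
#'
#' The nucleus' neurons are replaced by Poisson spike generators with the
#' given mean rate at the same coordinates; outgoing projections are kept,
#' incoming synapses become inert. Used by the conductance-calibration
#' stages (GPe at 30.4 Hz, STN at 11.8 Hz) and available for reduced-circuit
#' experiments. `rate = 0` silences the nucleus entirely.
#'
#' @param circuit an [build_circuit()] object.
#' @param nucleus `"stn"` or `"gpe"`.
#' @param rate mean firing rate in Hz.
#' @return The modified circuit.
#' @export
substitute_poisson <- function(circuit, nucleus, rate) {
  if (!nucleus %in% c("stn", "gpe")) stop("unknown nucleus: ", nucleus)
  circuit[[paste0(nucleus, "_mode")]] <- "poisson"
  circuit[[paste0(nucleus, "_rate")]] <- rate
  circuit
}

#' Indices of the centre subset of a nucleus
#'
#' Neurons with coordinates in `(-L/6, L/6)` -- the centre third of the
#' feature axis. Mean rates are measured on this subset to avoid boundary
#' effects of the finite topographic axis.
#'
#' @param circuit a circuit object.
#' @param nucleus nucleus name.
#' @return Integer vector of 1-based neuron indices.
#' @export
centre_subset <- function(circuit, nucleus) {
  lay <- circuit$layouts[[nucleus]]
  which(abs(lay$coords) < lay$L / 6)
}

# CSR form of a projection graph for the compiled engine (0-based)
graph_to_csr <- function(graph, n_pre) {
  o <- order(graph$pre, graph$post)
  pre <- graph$pre[o]
  tgt <- graph$post[o] - 1L
  ptr <- c(0L, cumsum(tabulate(pre, nbins = n_pre)))
  list(ptr = as.integer(ptr), tgt = as.integer(tgt))
}
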