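#' Place neurons on the feature axis
#'
#' Neurons of each nucleus sit equidistantly on the feature (somatotopic)
#' axis `[-L/2, L/2]`, plus small per-neuron uniform offsets in
#' `[0, offset_scale]` that make all pairwise distances distinct so that
#' nearest-neighbour wiring has no ties. Offsets are much smaller than the
#' grid spacing, so ordering is preserved.
#'
#' @param n number of neurons (`>= 2`).
#' @param L axis length (default 1).
#' @param offset_scale maximal random coordinate offset; `1e-4 * L` for
#'   CTX/MSN generators and `1e-3 * L` for STN/GPe neurons.
#' @return Object of class `population_layout`: list with `n`, `coords`
#'   (sorted), `L`, `offset_scale`.
#' @export
place_neurons <- function(n, L = 1, offset_scale = 1e-3 * L) {
  if (n < 2) stop("'n' must be >= 2")
  grid <- seq(-L / 2, L / 2, length.out = n)
  coords <- grid + stats::runif(n, 0, offset_scale)
  structure(list(n = n, coords = coords, L = L, offset_scale = offset_scale),
            class = "population_layout")
}

#' @export
print.population_layout <- function(x, ...) {
  cat(sprintf("<population_layout> n=%d on [%.2f, %.2f], offsets <= %g\n",
              x$n, -x$L / 2, x$L / 2, x$offset_scale))
  invisible(x)
}

new_network_graph <- function(pre, post, displaced, type) {
  structure(
    data.frame(pre = pre, post = post, displaced = displaced),
    type = type, class = c("network_graph", "data.frame"))
}

#' Build an intact topographic (N) projection
#'
#' Each presynaptic neuron connects to the `n_out` postsynaptic neurons with
#' the smallest coordinate difference `|s_post - s_pre|`; the random layout
#' offsets break all ties. With `exclude_self = TRUE` (used for recurrent
#' GPe->GPe wiring) a neuron never targets itself.
#'
#' @param pre,post [place_neurons()] layouts of the pre-/postsynaptic nuclei.
#' @param n_out fixed out-degree per presynaptic neuron.
#' @param exclude_self drop the identical index as a candidate (recurrent
#'   projections only).
#' @return A `network_graph`: data frame with columns `pre`, `post`
#'   (1-based indices) and `displaced` (logical, all `FALSE` here).
#' @export
build_n_network <- function(pre, post, n_out, exclude_self = FALSE) {
  max_out <- post$n - as.integer(exclude_self)
  if (n_out > max_out)
    stop("'n_out' exceeds the number of available postsynaptic neurons")
  edges <- lapply(seq_len(pre$n), function(i) {
    dist <- abs(post$coords - pre$coords[i])
    if (exclude_self) dist[i] <- Inf
    order(dist)[seq_len(n_out)]
  })
  new_network_graph(rep(seq_len(pre$n), each = n_out), unlist(edges),
                    FALSE, "N")
}

#' Displace a fraction of connections (D-network)
#'
#' A uniformly chosen portion `P` of the edges (exactly `round(P * n_edges)`
#' of them) is rewired so that each displaced edge targets the postsynaptic
#' neuron minimising `|(s_post - d) - s_pre|`, i.e. targets shifted by `d`
#' along the feature axis. Displaced edges from the same presynaptic neuron
#' take the nearest *distinct* shifted targets so that per-neuron target
#' lists stay free of duplicates; shifted coordinates beyond the axis end
#' clamp to the outermost neuron.
#'
#' @param graph a `network_graph` (typically from [build_n_network()]).
#' @param pre,post the layouts the graph was built from.
#' @param P fraction of edges to displace, in `[0, 1]`.
#' @param d displacement along the feature axis (default `0.15 * L`).
#' @param exclude_self as in [build_n_network()].
#' @return The rewired `network_graph` with `displaced` flags set.
#' @export
build_d_network <- function(graph, pre, post, P = 0.1, d = 0.15 * post$L,
                            exclude_self = FALSE) {
  stopifnot(P >= 0, P <= 1)
  n_edges <- nrow(graph)
  n_disp <- round(P * n_edges)
  if (n_disp == 0) return(graph)
  idx <- sample.int(n_edges, n_disp)
  for (i in split(idx, graph$pre[idx])) {
    p <- graph$pre[i[1]]
    dist <- abs((post$coords - d) - pre$coords[p])
    if (exclude_self) dist[p] <- Inf
    graph$post[i] <- order(dist)[seq_along(i)]
    graph$displaced[i] <- TRUE
  }
  attr(graph, "type") <- "D"
  graph
}

#' Build a skipping (S) projection
#'
#' As [build_n_network()], except that each presynaptic neuron projects only
#' to every second postsynaptic neuron, starting from the one with minimal
#' coordinate difference: candidates are the postsynaptic neurons whose index
#' has the same parity as that nearest neuron, and the `n_out` nearest
#' candidates are taken. The projection span is therefore about twice that
#' of the N-network for the same out-degree.
#'
#' @inheritParams build_n_network
#' @return A `network_graph`.
#' @export
build_s_network <- function(pre, post, n_out, exclude_self = FALSE) {
  if (n_out > ceiling(post$n / 2))
    stop("'n_out' exceeds the number of available (every second) targets")
  edges <- lapply(seq_len(pre$n), function(i) {
    dist <- abs(post$coords - pre$coords[i])
    if (exclude_self) dist[i] <- Inf
    nearest <- which.min(dist)
    cand <- seq_len(post$n)[seq_len(post$n) %% 2 == nearest %% 2]
    cand <- cand[is.finite(dist[cand])]
    cand[order(dist[cand])[seq_len(n_out)]]
  })
  new_network_graph(rep(seq_len(pre$n), each = n_out), unlist(edges),
                    FALSE, "S")
}

#' Validate a projection graph
#'
#' Checks the structural contracts of a wiring graph -- exact out-degree,
#' distinct targets per presynaptic neuron, no self-loops in recurrent
#' projections -- and reports the in-degree histogram (the substrate of the
#' firing-rate multimodality seen in displaced networks).
#'
#' @param graph a `network_graph`.
#' @param n_pre,n_post population sizes.
#' @param n_out expected out-degree.
#' @param recurrent if `TRUE`, self-loops are violations.
#' @return List with `ok`, character vector `violations`, `out_degree` and
#'   `in_degree` tables.
#' @export
validate_graph <- function(graph, n_pre, n_post, n_out, recurrent = FALSE) {
  violations <- character()
  out_deg <- tabulate(graph$pre, nbins = n_pre)
  if (any(out_deg != n_out))
    violations <- c(violations, sprintf(
      "%d presynaptic neuron(s) with out-degree != %d", sum(out_deg != n_out),
      n_out))
  dup <- any(vapply(split(graph$post, graph$pre), anyDuplicated, 0L) > 0)
  if (dup)
    violations <- c(violations, "duplicate targets for some presynaptic neuron")
  if (recurrent && any(graph$pre == graph$post))
    violations <- c(violations, "self-loop in recurrent projection")
  if (any(graph$post < 1 | graph$post > n_post))
    violations <- c(violations, "postsynaptic index out of range")
  list(ok = length(violations) == 0, violations = violations,
       out_degree = out_deg, in_degree = tabulate(graph$post, nbins = n_post))
}
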