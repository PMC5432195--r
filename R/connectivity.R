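#' Build the network connectivity
#'
#' Realizes the sparse random connectivity of the two subnetworks from a
#' parameter set and the `connectivity` seed. Each ordered pair of neurons
#' within a subnetwork is connected independently with probability `K/N`
#' (self-connections excluded), so realized in- and out-degrees are
#' Binomial(`N`, `K/N`). Weights are `+1/sqrt(K)` from excitatory sources,
#' `-J_E/sqrt(K)` from inhibitory onto excitatory, and `-J_I/sqrt(K)` from
#' inhibitory onto inhibitory neurons. In `mirrored` mode the second
#' subnetwork's adjacency is an exact copy of the first's.
#'
#' The mutual inhibition between subnetworks is either implicit (all-to-all
#' mode: every inhibitory neuron inhibits every excitatory neuron of the
#' other subnetwork with uniform weight `-J_tilde*sqrt(K)/N`, which the
#' simulator evaluates exactly from the population counts) or explicit
#' sparse synapses of weight `-J_tilde/sqrt(K)` with probability `K/N`
#' (sparse mode; mirrored networks share one realized cross pattern).
#'
#' @param params A [network_params()] object.
#' @return A `"connectivity"` object: list with `edges` (adjacency groups,
#'   each with source/target population, CSR offsets, target indices and a
#'   scalar weight), `params`, and `cross_mode`.
#' @export
build_connectivity <- function(params) {
  p <- validate_params(params)
  N <- p$N
  prob <- p$K / N
  sqrtK <- sqrt(p$K)
  w_within <- list(EE = 1 / sqrtK, IE = 1 / sqrtK,
                   EI = -p$J_E / sqrtK, II = -p$J_I / sqrtK)
  set.seed(p$seeds$connectivity)
  make_group <- function(src, tgt, w, pattern = NULL) {
    if (is.null(pattern)) pattern <- cpp_build_edges(N, prob, src == tgt)
    list(src_pop = src, tgt_pop = tgt, off = pattern$off, tgt = pattern$tgt,
         w = w, pattern = pattern)
  }
  sub1 <- list(make_group(1L, 1L, w_within$EE),
               make_group(1L, 2L, w_within$IE),
               make_group(2L, 1L, w_within$EI),
               make_group(2L, 2L, w_within$II))
  remap <- function(g, src, tgt) { g$src_pop <- src; g$tgt_pop <- tgt; g }
  if (p$mirrored) {
    sub2 <- list(remap(sub1[[1]], 3L, 3L), remap(sub1[[2]], 3L, 4L),
                 remap(sub1[[3]], 4L, 3L), remap(sub1[[4]], 4L, 4L))
  } else {
    sub2 <- list(make_group(3L, 3L, w_within$EE),
                 make_group(3L, 4L, w_within$IE),
                 make_group(4L, 3L, w_within$EI),
                 make_group(4L, 4L, w_within$II))
  }
  edges <- c(sub1, sub2)
  if (p$cross_mode == "sparse") {
    w_cross <- -p$J_tilde / sqrtK
    g23 <- make_group(2L, 3L, w_cross)
    g41 <- if (p$mirrored) remap(g23, 4L, 1L)
           else make_group(4L, 1L, w_cross)
    edges <- c(edges, list(g23, g41))
  }
  edges <- lapply(edges, function(g) { g$pattern <- NULL; g })
  structure(list(edges = edges, params = p, cross_mode = p$cross_mode),
            class = "connectivity")
}

#' Per-synapse weight of the all-to-all cross-inhibition
#'
#' In all-to-all mode every inhibitory neuron projects to every excitatory
#' neuron of the other subnetwork with weight `-J_tilde*sqrt(K)/N`, so that
#' when the opposing inhibitory population has mean activity `m` the total
#' cross input to one excitatory neuron is exactly `-J_tilde*sqrt(K)*m`.
#'
#' @param params A [network_params()] object with `cross_mode =
#'   "all_to_all"`.
#' @return The scalar synaptic weight.
#' @export
cross_input_weight <- function(params) {
  if (params$cross_mode != "all_to_all")
    stop("cross_input_weight is defined only in all_to_all cross mode")
  -params$J_tilde * sqrt(params$K) / params$N
}

#' @export
print.connectivity <- function(x, ...) {
  p <- x$params
  nsyn <- sum(vapply(x$edges, function(g) length(g$tgt), numeric(1)))
  cat(sprintf("Connectivity: N = %d, K = %d, %s cross mode, %s\n",
              p$N, p$K, x$cross_mode,
              if (p$mirrored) "mirrored" else "independent subnetworks"))
  cat(sprintf("  %d explicit synapses in %d groups\n", nsyn, length(x$edges)))
  invisible(x)
}

#' Realized in-degree distribution of an adjacency group
#'
#' Counts, for one edge group, the number of presynaptic partners of each
#' target neuron. Useful for checking the Binomial(N, K/N) invariant.
#'
#' @param conn A `"connectivity"` object.
#' @param src_pop,tgt_pop Population indices (1-4) selecting the group.
#' @return Integer vector of length `N` of in-degrees.
#' @export
in_degrees <- function(conn, src_pop, tgt_pop) {
  g <- find_group(conn, src_pop, tgt_pop)
  tabulate(g$tgt + 1L, nbins = conn$params$N)
}

find_group <- function(conn, src_pop, tgt_pop) {
  for (g in conn$edges)
    if (g$src_pop == src_pop && g$tgt_pop == tgt_pop) return(g)
  stop(sprintf("no edge group %d -> %d", src_pop, tgt_pop))
}

# dense weight matrix of one group (tiny networks only; test oracle)
group_dense <- function(g, N) {
  W <- matrix(0, N, N) # [target, source]
  for (j in seq_len(N)) {
    ks <- if (g$off[j] < g$off[j + 1]) (g$off[j] + 1L):g$off[j + 1L] else integer(0)
    W[g$tgt[ks] + 1L, j] <- g$w
  }
  W
}
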