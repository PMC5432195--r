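# Shared fixtures: small networks are built fresh (cheaply) inside tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_params <- function(N = 60L, K = 12L, ...) {
  network_params(N = N, K = K,
                 seeds = list(connectivity = 7L, schedule = 8L, init = 9L),
                 ...)
}

desk_params <- function(N = 4000L, K = 100L, seed = 1L, ...) {
  network_params(N = as.integer(N), K = as.integer(K),
                 seeds = list(connectivity = seed, schedule = seed + 1L,
                              init = seed + 2L), ...)
}

# dense within-subnetwork weight matrix from the edge lists (test oracle)
dense_weights <- function(conn) {
  N <- conn$params$N
  W <- matrix(0, 4 * N, 4 * N)
  for (g in conn$edges) {
    for (j in seq_len(N)) {
      ks <- if (g$off[j] < g$off[j + 1]) (g$off[j] + 1L):g$off[j + 1L]
            else integer(0)
      if (length(ks))
        W[(g$tgt_pop - 1L) * N + g$tgt[ks] + 1L, (g$src_pop - 1L) * N + j] <-
          W[(g$tgt_pop - 1L) * N + g$tgt[ks] + 1L, (g$src_pop - 1L) * N + j] + g$w
    }
  }
  W
}

# reference total input computed in plain R from the dense matrix
dense_inputs <- function(state, conn, params) {
  p <- params
  N <- p$N
  W <- dense_weights(conn)
  u <- as.vector(W %*% state$sigma) + rep(sqrt(p$K) * pop_E0_test(p) - p$T,
                                          each = N)
  if (p$cross_mode == "all_to_all") {
    cw <- cross_input_weight(p)
    u[1:N] <- u[1:N] + cw * state$counts[4]
    u[(2 * N + 1):(3 * N)] <- u[(2 * N + 1):(3 * N)] + cw * state$counts[2]
  }
  u
}

pop_E0_test <- function(p) c(p$E0, 0, p$E0, 0)
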