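#' Initialize the network state
#'
#' Draws each neuron's binary state independently as Bernoulli with its
#' population's target probability, computes the cached recurrent inputs by
#' brute force, and resets the clock. The target activities are given
#' either directly (`mode = "random"`, `m_target`) or as a position `x` on
#' the infinite-`K` line of balanced states (`mode = "attractor_point"`).
#'
#' @param conn A [build_connectivity()] object.
#' @param params A [network_params()] object.
#' @param mode `"random"` or `"attractor_point"`.
#' @param m_target Length-4 activity vector in \[0, 1\] (random mode).
#' @param x Position along the line (attractor_point mode).
#' @return A `"network_state"`: list with `sigma` (integer 0/1, length
#'   `4N`), `u_rec` (cached recurrent input per neuron), `counts`, `t`,
#'   `xi` (input-noise state).
#' @export
init_state <- function(conn, params, mode = c("random", "attractor_point"),
                       m_target = NULL, x = NULL) {
  mode <- match.arg(mode)
  p <- params
  if (mode == "attractor_point") {
    if (is.null(x)) x <- line_x_symmetric(p)
    m_target <- line_kinf(x, params_on_line(p))
  }
  stopifnot(length(m_target) == 4L, all(m_target >= 0 & m_target <= 1))
  set.seed(p$seeds$init)
  sigma <- as.integer(stats::runif(4L * p$N) < rep(m_target, each = p$N))
  state_from_sigma(sigma, conn, p)
}

state_from_sigma <- function(sigma, conn, params) {
  N <- params$N
  counts <- as.integer(vapply(1:4, function(q) sum(sigma[((q - 1) * N + 1):(q * N)]),
                              numeric(1)))
  structure(list(sigma = sigma,
                 u_rec = cpp_urec_bruteforce(conn$edges, sigma, N),
                 counts = counts, t = 0, xi = c(0, 0)),
            class = "network_state")
}

params_c <- function(params) {
  p <- params
  noise <- !is.null(p$input_noise)
  list(N = p$N, K = as.numeric(p$K), J_tilde = p$J_tilde, E0 = p$E0,
       tau_E = p$tau_E, tau_I = p$tau_I, T = as.numeric(p$T),
       all_to_all = p$cross_mode == "all_to_all",
       noise_on = noise,
       tau_noise = if (noise) p$input_noise$tau_noise else 1,
       sigma_noise = if (noise) p$input_noise$sigma_noise else 0,
       noise_independent = noise && isTRUE(p$input_noise$independent))
}

#' Run the asynchronous binary dynamics
#'
#' Advances the event-driven dynamics for `duration` ms. Update times
#' follow a global Poisson clock with total rate `2N/tau_E + 2N/tau_I`; at
#' each event one neuron is redrawn as `sigma = Theta(u)` from its current
#' total input (cached recurrent input plus the exact all-to-all
#' cross-inhibition from the opposing counts, the feedforward drive, and
#' the shared input noise if enabled). `Theta(0) = 0` (strict threshold).
#' Population mean activities are sampled every `dt_rec` ms (state as of
#' the most recent event before each sample time). With
#' `mirror_schedule = TRUE` one schedule is drawn for the first subnetwork
#' and applied to the homologous neurons of both, which preserves the exact
#' symmetry of mirrored connectivity.
#'
#' @param state A `"network_state"` from [init_state()].
#' @param conn The matching [build_connectivity()] object.
#' @param params A [network_params()] object.
#' @param duration Simulated time (ms).
#' @param dt_rec Sampling interval for the population trace (ms); 0
#'   disables trace recording.
#' @param record_spikes_n Record 0-to-1 transitions of the first
#'   `record_spikes_n` neurons of each population (0: none).
#' @param record_states_n Record binary-state snapshots of the first
#'   `record_states_n` neurons per population every `dt_state` ms.
#' @param dt_state Snapshot interval (ms, defaults to `dt_rec`).
#' @param mirror_schedule Apply one update schedule to both subnetworks.
#' @param refresh_every Brute-force recompute of the cached inputs every
#'   this many events, to cap floating-point drift of the additive updates.
#' @param max_events Stop after this many events (negative: unlimited).
#' @param reseed If `TRUE` (default), seed R's RNG with the `schedule` seed
#'   first; set `FALSE` to continue an ongoing stream.
#' @return List with `trace` (a `"population_trace"`), `spikes` (a
#'   `"spike_record"` data frame), `states` (snapshot matrix, neurons in
#'   columns grouped by population), `state_times`, `state` (final
#'   `"network_state"`), `n_events`, `n_flips`.
#' @export
run_network <- function(state, conn, params, duration, dt_rec = 1,
                        record_spikes_n = 0L, record_states_n = 0L,
                        dt_state = dt_rec, mirror_schedule = FALSE,
                        refresh_every = 1e6, max_events = -1,
                        reseed = TRUE) {
  stopifnot(inherits(state, "network_state"), duration > 0)
  if (reseed) set.seed(params$seeds$schedule)
  res <- cpp_run(conn$edges, params_c(params), state, duration, dt_rec,
                 list(mirror_schedule = mirror_schedule,
                      record_spikes_n = as.integer(record_spikes_n),
                      record_states_n = as.integer(record_states_n),
                      dt_state = dt_state,
                      refresh_every = refresh_every,
                      max_events = max_events))
  new_state <- structure(list(sigma = res$sigma, u_rec = res$u_rec,
                              counts = res$counts, t = res$t, xi = res$xi),
                         class = "network_state")
  spikes <- structure(data.frame(time = res$spike_t, population = res$spike_pop,
                                 neuron = res$spike_idx),
                      class = c("spike_record", "data.frame"))
  trace <- if (dt_rec > 0) population_trace(res$times, res$m) else NULL
  states <- NULL
  if (record_states_n > 0) {
    states <- matrix(as.integer(res$states), nrow = nrow(res$states))
    attr(states, "times") <- res$state_times
    attr(states, "pop") <- rep(1:4, each = record_states_n)
  }
  list(trace = trace, spikes = spikes, states = states,
       state_times = res$state_times, state = new_state,
       n_events = res$n_events, n_flips = res$n_flips)
}

#' Advance the dynamics by a fixed number of events
#'
#' @inheritParams run_network
#' @param n_events Number of update events to apply.
#' @return Same structure as [run_network()] (no trace recording).
#' @export
step_events <- function(state, conn, params, n_events, reseed = TRUE) {
  run_network(state, conn, params, duration = Inf, dt_rec = 0,
              max_events = n_events, reseed = reseed)
}

#' Flip one neuron's state
#'
#' Toggles the binary state of one neuron and propagates the change to all
#' postsynaptic cached inputs and the population counts. Used to build
#' perturbed-replica ensembles that share an update schedule.
#'
#' @param state A `"network_state"`.
#' @param conn The matching connectivity.
#' @param population Population index (1-4).
#' @param index Neuron index within the population (1-based).
#' @return The modified `"network_state"`.
#' @export
flip_neuron <- function(state, conn, population, index) {
  N <- conn$params$N
  if (!(population %in% 1:4) || index < 1 || index > N)
    stop("population must be in 1:4 and index in 1:N")
  at <- (population - 1L) * N + index
  d <- if (state$sigma[at] == 1L) -1L else 1L
  state$sigma[at] <- state$sigma[at] + d
  state$counts[population] <- state$counts[population] + d
  for (g in conn$edges) {
    if (g$src_pop != population) next
    ks <- if (g$off[index] < g$off[index + 1L])
      (g$off[index] + 1L):g$off[index + 1L] else integer(0)
    if (length(ks))
      state$u_rec[(g$tgt_pop - 1L) * N + g$tgt[ks] + 1L] <-
        state$u_rec[(g$tgt_pop - 1L) * N + g$tgt[ks] + 1L] + d * g$w
  }
  state
}

#' Total input to every neuron, recomputed by brute force
#'
#' Evaluates each neuron's total input (recurrent sum over all explicit
#' synapses, the exact all-to-all cross-inhibition, the feedforward drive
#' `sqrt(K)*E0`, the current input noise, minus the threshold) by direct
#' summation, independent of the incrementally maintained cache.
#'
#' @param state A `"network_state"`.
#' @param conn The matching connectivity.
#' @param params A [network_params()] object.
#' @param recompute If `TRUE` (default) the recurrent part is re-summed
#'   from scratch; otherwise the cached values are used.
#' @return Numeric vector of length `4N` of total inputs.
#' @export
neuron_inputs <- function(state, conn, params, recompute = TRUE) {
  p <- params
  N <- p$N
  u_rec <- if (recompute) cpp_urec_bruteforce(conn$edges, state$sigma, N)
           else state$u_rec
  base <- rep(sqrt(p$K) * pop_E0(p) - p$T, each = N)
  u <- u_rec + base
  if (p$cross_mode == "all_to_all") {
    cw <- cross_input_weight(p)
    u[1:N] <- u[1:N] + cw * state$counts[4]
    u[(2 * N + 1):(3 * N)] <- u[(2 * N + 1):(3 * N)] + cw * state$counts[2]
  }
  if (!is.null(p$input_noise)) {
    u[1:N] <- u[1:N] + sqrt(p$K) * state$xi[1]
    u[(2 * N + 1):(3 * N)] <- u[(2 * N + 1):(3 * N)] + sqrt(p$K) * state$xi[2]
  }
  u
}

#' Population activity trace
#'
#' Container for population mean activities sampled on a uniform grid.
#'
#' @param times Sample times (ms).
#' @param m Matrix with one row per sample and four columns (populations).
#' @return A `"population_trace"`.
#' @export
population_trace <- function(times, m) {
  m <- as.matrix(m)
  colnames(m) <- c("m1", "m2", "m3", "m4")
  structure(list(times = as.numeric(times), m = m),
            class = "population_trace")
}

#' @export
print.population_trace <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Population trace: %d samples, t = %.6g .. %.6g ms\n",
              n, x$times[1], x$times[n]))
  cat("  mean activities:", sprintf("%.4f", colMeans(x$m)), "\n")
  invisible(x)
}

#' Inter-spike intervals per neuron
#'
#' @param spikes A `"spike_record"` data frame.
#' @param population Population to select.
#' @return List of numeric vectors of ISIs (ms), one per neuron that fired
#'   at least twice.
#' @export
spike_isis <- function(spikes, population = 1L) {
  s <- spikes[spikes$population == population, ]
  out <- lapply(split(s$time, s$neuron), function(tt) diff(sort(tt)))
  out[vapply(out, length, integer(1)) > 0]
}

#' One-line convenience simulation
#'
#' Builds the connectivity, initializes at a line position (the symmetric
#' point by default), and runs the dynamics.
#'
#' @param params A [network_params()] object.
#' @param duration Simulated time (ms).
#' @param x Initial position along the line of balanced states.
#' @param ... Passed to [run_network()].
#' @return As [run_network()], plus `conn`.
#' @export
simulate_network <- function(params, duration, x = NULL, ...) {
  conn <- build_connectivity(params)
  st <- init_state(conn, params, mode = "attractor_point", x = x)
  out <- run_network(st, conn, params, duration, ...)
  out$conn <- conn
  out
}
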