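#' Model parameters for the coupled balanced network
#'
#' Defines the full parameter set of a network of two mutually inhibiting
#' balanced subnetworks. Each subnetwork consists of one excitatory and one
#' inhibitory population of `N` binary neurons, wired randomly with
#' connection probability `K/N` and synaptic weights of magnitude
#' `J/sqrt(K)`. The inhibitory population of each subnetwork projects to the
#' excitatory population of the other, either with uniform weak weights
#' `-J_tilde*sqrt(K)/N` (all-to-all mode) or with sparse random synapses of
#' strength `-J_tilde/sqrt(K)` (sparse mode).
#'
#' Population indexing throughout the package is 1 = excitatory and
#' 2 = inhibitory of the first subnetwork, 3 = excitatory and 4 = inhibitory
#' of the second.
#'
#' @param N Neurons per population (positive integer).
#' @param K Mean in-degree per presynaptic population (positive integer,
#'   `K < N`). Within-subnetwork weights are `1/sqrt(K)` from excitatory
#'   neurons, `-J_E/sqrt(K)` and `-J_I/sqrt(K)` from inhibitory neurons onto
#'   excitatory and inhibitory targets respectively.
#' @param J_E Magnitude of the inhibitory-to-excitatory coupling within a
#'   subnetwork (dimensionless; must exceed `J_I`).
#' @param J_I Magnitude of the inhibitory-to-inhibitory coupling
#'   (dimensionless; must exceed 1).
#' @param J_tilde Magnitude of the mutual inhibition between subnetworks.
#'   `J_E - J_I` is the value at which the infinite-`K` steady-state system
#'   becomes singular, producing a line of balanced states.
#' @param E0 Feedforward drive to the excitatory populations; each excitatory
#'   neuron receives `sqrt(K)*E0`. Inhibitory populations receive no
#'   feedforward input.
#' @param tau_E,tau_I Mean inter-update intervals of excitatory and
#'   inhibitory neurons, in ms.
#' @param T Thresholds, a length-4 numeric vector (or a scalar recycled to
#'   all four populations).
#' @param cross_mode `"all_to_all"` (uniform weak cross-inhibition) or
#'   `"sparse"` (random cross synapses with probability `K/N`).
#' @param mirrored If `TRUE`, the second subnetwork's connectivity is an
#'   exact copy of the first's, which makes the symmetric fixed point exact.
#' @param input_noise `NULL`, or a list with elements `tau_noise` (ms),
#'   `sigma_noise`, and optionally `independent` (logical, default `FALSE`):
#'   an Ornstein-Uhlenbeck process `tau_noise * dxi/dt = -xi + sigma_noise *
#'   eta(t)` added to the drive `E0` of the excitatory populations, shared
#'   between the two subnetworks unless `independent`.
#' @param seeds List with integer elements `connectivity`, `schedule`,
#'   `init`; the three independent random streams. Keeping `schedule` fixed
#'   while varying the initial state reproduces the perturbed-replica
#'   (chaos) protocol.
#'
#' @return An object of class `"network_params"`.
#' @examples
#' p <- network_params(N = 1000, K = 100)
#' p$J_tilde # J_E - J_I by default
#' @export
network_params <- function(N = 10000L, K = 100L, J_E = 4, J_I = 2.5,
                           J_tilde = J_E - J_I, E0 = 0.3,
                           tau_E = 10, tau_I = 8, T = 1,
                           cross_mode = c("all_to_all", "sparse"),
                           mirrored = TRUE, input_noise = NULL,
                           seeds = list(connectivity = 101L,
                                        schedule = 202L,
                                        init = 303L)) {
  cross_mode <- match.arg(cross_mode)
  if (length(T) == 1L) T <- rep(T, 4L)
  p <- structure(list(
    N = as.integer(N), K = as.integer(K), J_E = J_E, J_I = J_I,
    J_tilde = J_tilde, E0 = E0, tau_E = tau_E, tau_I = tau_I, T = T,
    cross_mode = cross_mode, mirrored = isTRUE(mirrored),
    input_noise = input_noise, seeds = seeds
  ), class = "network_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(is.list(p))
  if (p$N <= 0L || p$K <= 0L) stop("N and K must be positive integers")
  if (p$K >= p$N) stop("K must be smaller than N (sparse regime K << N)")
  if (!(p$J_E > p$J_I)) stop("couplings must satisfy J_E > J_I")
  if (!(p$J_I > 1)) stop("couplings must satisfy J_I > 1")
  xmax <- p$J_I * p$E0 / (p$J_E - p$J_I)
  if (!(xmax > 0 && xmax < 1))
    stop("drive must satisfy 0 < J_I*E0/(J_E - J_I) < 1 for a valid line")
  if (!(p$tau_E > 0 && p$tau_I > 0)) stop("time constants must be positive")
  if (length(p$T) != 4L || any(!is.finite(p$T)))
    stop("T must be four finite thresholds")
  if (!is.null(p$input_noise)) {
    stopifnot(is.list(p$input_noise),
              p$input_noise$tau_noise > 0, p$input_noise$sigma_noise >= 0)
  }
  for (s in c("connectivity", "schedule", "init"))
    if (is.null(p$seeds[[s]])) stop("missing seed stream: ", s)
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat("Coupled balanced network parameters\n")
  cat(sprintf("  N = %d per population, K = %d\n", x$N, x$K))
  cat(sprintf("  J_E = %g, J_I = %g, J_tilde = %g, E0 = %g\n",
              x$J_E, x$J_I, x$J_tilde, x$E0))
  cat(sprintf("  tau_E = %g ms, tau_I = %g ms, T = (%s)\n",
              x$tau_E, x$tau_I, paste(x$T, collapse = ", ")))
  cat(sprintf("  cross mode: %s, mirrored: %s\n", x$cross_mode, x$mirrored))
  if (!is.null(x$input_noise))
    cat(sprintf("  input noise: tau = %g ms, sigma = %g\n",
                x$input_noise$tau_noise, x$input_noise$sigma_noise))
  invisible(x)
}

# per-population vectors used across modules
pop_tau <- function(p) c(p$tau_E, p$tau_I, p$tau_E, p$tau_I)
pop_E0 <- function(p) c(p$E0, 0, p$E0, 0)
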