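#' Mildly detuned mutual inhibition for stable desk-scale runs
#'
#' Finite networks tuned exactly to the mean-field singular point sit at
#' the edge of stability: the chaotic noise is strong at small `N` and the
#' effective zero crossing of the drift is slightly shifted from the
#' mean-field value, so an exactly tuned simulation can drift to the ends
#' of the line. Stochastic experiments therefore run at the coupling where
#' the mean-field slow eigenvalue equals `lambda_target` (in 1/tau_E;
#' default -0.25, giving a slow time scale of a few hundred ms at desk
#' scale while remaining safely on the stable side).
#'
#' @param params A [network_params()] object.
#' @param K In-degree.
#' @param lambda_target Desired mean-field slow eigenvalue (1/tau_E, < 0).
#' @return The coupling `J_tilde` with that eigenvalue.
#' @export
detuned_jtilde <- function(params, K = params$K, lambda_target = -0.25) {
  stopifnot(lambda_target < 0)
  lo <- params$J_E - params$J_I
  hi <- tune_jtilde(params, K)
  stats::uniroot(function(jt) lambda_slow(params, K, jt) - lambda_target,
                 c(lo + 1e-9, hi), tol = 1e-9)$root
}

#' Scripted experiment drivers
#'
#' Each driver reproduces one of the study protocols at a configurable
#' scale and returns its result tables; with `out_dir` set, every table is
#' written as TSV together with a manifest. Durations and trial counts are
#' desk-sized by default and scale linearly with `scale`; full-scale
#' population sizes must be requested explicitly with `full_scale = TRUE`
#' (hours of compute).
#'
#' Available experiments:
#' \describe{
#'   \item{`tuning`}{Nullclines at and away from tuning, eigenvalue versus
#'     coupling for several `K`, and noisy mean-field trajectories (the
#'     infinite-`N` illustration of the line).}
#'   \item{`single_neuron`}{Resting-state run; spike raster and ISI
#'     statistics of excitatory neurons.}
#'   \item{`memory_decay`}{Trials initialized on the line at two positions;
#'     mean and SD of the projection over trials, plus its MSD.}
#'   \item{`drift_diffusion`}{Conditional moments F and G along the
#'     attractor, OU fit, the short-lag prediction from single-neuron
#'     autocorrelations, and the 1/N scaling of D.}
#'   \item{`single_covariance`}{Population covariances of one balanced
#'     subnetwork at two sizes, scaled by N (collapse).}
#'   \item{`coupled_covariance`}{Slow population cross-covariances in the
#'     coupled network and pairwise-averaged covariances from n recorded
#'     neurons.}
#'   \item{`chaos`}{Perturbed-replica ensemble (identical schedule and
#'     connectivity, one neuron flipped per population); across-replica
#'     variance of X versus time with an OU fit.}
#'   \item{`nonmirrored`}{Drift/diffusion with independently drawn
#'     subnetwork connectivity.}
#'   \item{`sparse_cross`}{Drift/diffusion with sparse random
#'     cross-inhibition.}
#'   \item{`input_noise`}{Diffusion under shared Ornstein-Uhlenbeck input
#'     noise of increasing amplitude.}
#' }
#'
#' @param name Experiment name (see Details).
#' @param scale Scale factor for durations/trials (default 1 = desk scale).
#' @param N,K Population size and in-degree overrides.
#' @param seed Base seed; the three named streams are derived from it.
#' @param full_scale Allow full-scale `N`/`K` (long-running); without it,
#'   requests with `N > 2e4` or `K > 1000` are refused.
#' @param out_dir Optional output directory for TSV artifacts.
#' @return Named list of data frames (invisibly writes TSVs if `out_dir`).
#' @export
run_experiment <- function(name, scale = 1, N = NULL, K = NULL, seed = 1L,
                           full_scale = FALSE, out_dir = NULL) {
  drivers <- list(
    tuning = exp_tuning, single_neuron = exp_single_neuron,
    memory_decay = exp_memory_decay, drift_diffusion = exp_drift_diffusion,
    single_covariance = exp_single_covariance,
    coupled_covariance = exp_coupled_covariance, chaos = exp_chaos,
    nonmirrored = exp_nonmirrored, sparse_cross = exp_sparse_cross,
    input_noise = exp_input_noise)
  if (!name %in% names(drivers))
    stop("unknown experiment: ", name, " (available: ",
         paste(names(drivers), collapse = ", "), ")")
  if (!full_scale) {
    if (!is.null(N) && N > 2e4)
      stop("N > 20000 requires full_scale = TRUE")
    if (!is.null(K) && K > 1000)
      stop("K > 1000 requires full_scale = TRUE")
  }
  res <- drivers[[name]](scale = scale, N = N, K = K, seed = as.integer(seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res))
      if (is.data.frame(res[[nm]]))
        write_table_artifact(res[[nm]], file.path(out_dir,
                                                  paste0(name, "_", nm, ".tsv")))
  }
  res
}

exp_seeds <- function(seed) list(connectivity = seed, schedule = seed + 1L,
                                 init = seed + 2L)

# shared setup: coupled network at the detuned stable coupling
desk_network <- function(N, K, seed, lambda_target = -0.25, ...) {
  p <- network_params(N = N, K = K, seeds = exp_seeds(seed), ...)
  p$J_tilde <- detuned_jtilde(p, K, lambda_target)
  p
}

exp_tuning <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  K <- K %||% 1000L
  p <- network_params(N = 2L * K, K = K, seeds = exp_seeds(seed))
  jt_star <- tune_jtilde(p, K)
  grid <- seq(0.05, 0.45, length.out = max(9, round(17 * scale)))
  p_tuned <- p; p_tuned$J_tilde <- jt_star
  nc_plain <- nullclines(p, K, grid)
  nc_tuned <- nullclines(p_tuned, K, grid)
  lam <- do.call(rbind, lapply(c(100L, 500L, 1000L, 5000L), function(Kk) {
    jts <- tune_jtilde(p, Kk)
    cbind(K = Kk, lambda_vs_jtilde(p, Kk, seq(jts - 0.02, jts + 0.01,
                                              length.out = 7)))
  }))
  set.seed(seed)
  sigma <- 1e-2 * sqrt(10)
  m0 <- line_kinf(line_x_symmetric(p), params_on_line(p))
  tr_tuned <- integrate_mf(m0, p_tuned, duration = 2000 * scale,
                           noise_sigma = sigma, dt = 0.05, dt_rec = 1, K = K)
  tr_plain <- integrate_mf(m0, p, duration = 2000 * scale,
                           noise_sigma = sigma, dt = 0.05, dt_rec = 1, K = K)
  b <- projection_basis(p_tuned, K)
  list(jtilde_star = data.frame(K = K, jt_star = jt_star),
       nullclines_plain = nc_plain, nullclines_tuned = nc_tuned,
       lambda_table = lam,
       mf_noisy_tuned = data.frame(time = tr_tuned$times, tr_tuned$m,
                                   X = project(tr_tuned, b)),
       mf_noisy_plain = data.frame(time = tr_plain$times, tr_plain$m))
}

exp_single_neuron <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  N <- N %||% 10000L; K <- K %||% 500L
  p <- desk_network(N, K, seed)
  out <- simulate_network(p, duration = 10000 * scale, dt_rec = 1,
                          record_spikes_n = 100L)
  isis <- spike_isis(out$spikes, population = 1L)
  isis <- isis[lengths(isis) >= 10]
  cv <- vapply(isis, function(x) stats::sd(x) / mean(x), numeric(1))
  rate <- vapply(isis, function(x) 1000 / mean(x), numeric(1))
  list(spikes = utils::head(out$spikes, 50000),
       isi_stats = data.frame(neuron = as.integer(names(isis)),
                              n_isi = lengths(isis), cv = cv, rate_hz = rate),
       trace = data.frame(time = out$trace$times, out$trace$m))
}

exp_memory_decay <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  N <- N %||% 10000L; K <- K %||% 500L
  p <- desk_network(N, K, seed, lambda_target = -0.1)
  b <- projection_basis(p, K)
  conn <- build_connectivity(p)
  trials <- max(4L, round(10L * scale))
  dur <- 3000
  res <- list()
  for (x0 in c(0.05, 0.08)) {
    Xs <- vapply(seq_len(trials), function(tr) {
      p_t <- p
      p_t$seeds$init <- p$seeds$init + 1000L * tr
      p_t$seeds$schedule <- p$seeds$schedule + 1000L * tr
      st <- init_state(conn, p_t, mode = "attractor_point",
                       x = line_x_symmetric(p) + x0)
      out <- run_network(st, conn, p_t, duration = dur, dt_rec = 5)
      project(out$trace, b)
    }, numeric(dur / 5))
    tt <- seq(5, dur, by = 5)
    res[[sprintf("x0_%g", x0)]] <-
      data.frame(time = tt, mean_X = rowMeans(Xs),
                 sd_X = apply(Xs, 1, stats::sd),
                 msd = rowMeans((Xs - Xs[1, ])^2))
  }
  res
}

# one long resting-state run, projected
resting_X <- function(p, dur, dt_rec = 1, K = p$K, ...) {
  b <- projection_basis(p, K)
  out <- simulate_network(p, duration = dur, dt_rec = dt_rec, ...)
  list(X = project(out$trace, b), basis = b, out = out)
}

exp_drift_diffusion <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  N <- N %||% 10000L; K <- K %||% 100L
  p <- desk_network(N, K, seed)
  r <- resting_X(p, dur = 30000 * scale, dt_rec = 0.5,
                 record_states_n = min(N, 1000L), dt_state = 0.5)
  X <- r$X
  dd <- drift_diffusion(X, 0.5, X_grid = seq(-0.03, 0.03, by = 0.01),
                        lags = c(1, 2, 3, 5, 10, 20, 40, 80, 160, 320),
                        delta = 5e-3)
  g0 <- dd[abs(dd$X) < 1e-12 & !is.na(dd$G), ]
  fr <- fit_drift_rate(dd, dt = 20)
  fit <- fit_ou(g0$dt, g0$G, lambda_init = fr$lambda)
  qc <- autocorrelation_q(r$out$states, lags = seq(0.5, 5, by = 0.5),
                          slope_window = 2)
  pred <- short_time_G(qc$slope0, r$basis, N)
  scaling <- do.call(rbind, lapply(c(N / 2L, N, 2L * N), function(Nn) {
    pn <- p; pn$N <- as.integer(Nn)
    rn <- if (Nn == N) r else resting_X(pn, dur = 20000 * scale, dt_rec = 0.5)
    ddn <- drift_diffusion(rn$X, 0.5, X_grid = 0,
                           lags = c(5, 10, 20, 40, 80, 160, 320), delta = 5e-3)
    gn <- ddn[!is.na(ddn$G), ]
    fn <- fit_ou(gn$dt, gn$G, lambda_init = 1 / 100)
    data.frame(N = Nn, lambda = fn$lambda, D = fn$D, DN = fn$D * Nn,
               se_D = unname(fn$se["D"]))
  }))
  list(moments = dd, ou_fit = data.frame(lambda = fit$lambda, D = fit$D,
                                         lambda_F = fr$lambda),
       short_time = data.frame(dt = g0$dt, G_over_dt = g0$G / g0$dt,
                               prediction = pred),
       scaling = scaling)
}

# single balanced subnetwork: J_tilde = 0, both subnetworks independent
single_net_params <- function(N, K, seed, E_in) {
  p <- network_params(N = N, K = K, J_tilde = 0, E0 = E_in,
                      mirrored = FALSE, seeds = exp_seeds(seed))
  p
}

exp_single_covariance <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  N <- N %||% 10000L; K <- K %||% 100L
  lags <- seq(-50, 50, by = 1)
  out <- lapply(c(N %/% 2L, N), function(Nn) {
    p <- single_net_params(Nn, K, seed, 0.3)
    sim <- simulate_network(p, duration = 30000 * scale, dt_rec = 1,
                            x = line_x_symmetric(network_params(N = Nn, K = K)))
    sel <- sim$trace$times > 500
    ex <- sim$trace$m[sel, 1]; ih <- sim$trace$m[sel, 2]
    ex2 <- sim$trace$m[sel, 3]; ih2 <- sim$trace$m[sel, 4]
    data.frame(N = Nn, lag = lags,
               N_C_EE = Nn * (population_cross_covariance(ex, ex, lags, 1)$C +
                              population_cross_covariance(ex2, ex2, lags, 1)$C) / 2,
               N_C_EI = Nn * (population_cross_covariance(ex, ih, lags, 1)$C +
                              population_cross_covariance(ex2, ih2, lags, 1)$C) / 2,
               N_C_II = Nn * (population_cross_covariance(ih, ih, lags, 1)$C +
                              population_cross_covariance(ih2, ih2, lags, 1)$C) / 2)
  })
  list(collapse = do.call(rbind, out))
}

exp_coupled_covariance <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  N <- N %||% 10000L; K <- K %||% 100L
  p <- desk_network(N, K, seed)
  nrec <- 100L
  sim <- simulate_network(p, duration = 60000 * scale, dt_rec = 1,
                          record_states_n = nrec, dt_state = 66)
  sel <- sim$trace$times > 500
  m <- sim$trace$m[sel, ]
  lags <- seq(-400, 400, by = 10)
  pop_cov <- data.frame(
    lag = lags,
    C_E1E1 = population_cross_covariance(m[, 1], m[, 1], lags, 1)$C,
    C_E1I1 = population_cross_covariance(m[, 1], m[, 2], lags, 1)$C,
    C_E1I2 = population_cross_covariance(m[, 1], m[, 4], lags, 1)$C,
    C_E1E2 = population_cross_covariance(m[, 1], m[, 3], lags, 1)$C)
  S <- sim$out <- NULL
  st <- sim$states
  pop <- attr(st, "pop")
  lag66 <- seq(-396, 396, by = 66)
  pair_tab <- do.call(rbind, lapply(c(10L, 50L, nrec), function(n) {
    Si <- st[, which(pop == 1)[seq_len(n)], drop = FALSE]
    pc <- pair_cross_covariance(Si, NULL, lag66, 66)
    cbind(n = n, pc)
  }))
  list(population_covariance = pop_cov, pair_covariance = pair_tab)
}

exp_chaos <- function(scale = 1, N = NULL, K = NULL, seed = 1L,
                      params = NULL, trials = NULL, duration = NULL) {
  N <- N %||% 10000L; K <- K %||% 100L
  p <- params %||% desk_network(N, K, seed)
  trials <- trials %||% max(8L, round(30L * scale))
  duration <- duration %||% 2000
  b <- projection_basis(p, p$K)
  conn <- build_connectivity(p)
  st0 <- init_state(conn, p, mode = "attractor_point")
  Xs <- vapply(seq_len(trials), function(tr) {
    st <- st0
    if (tr > 1) # replica 1 is the unperturbed reference
      for (pp in 1:4) st <- flip_neuron(st, conn, pp, tr)
    out <- run_network(st, conn, p, duration = duration, dt_rec = 2)
    project(out$trace, b)
  }, numeric(duration / 2))
  ev <- ensemble_variance(Xs, times = seq(2, duration, by = 2))
  fit <- tryCatch({
    f <- fit_ou(ev$time, ev$var, lambda_init = 1 / 200, type = "variance")
    data.frame(lambda = f$lambda, D = f$D)
  }, error = function(e) data.frame(lambda = NA_real_, D = NA_real_))
  list(X_traces = data.frame(time = seq(2, duration, by = 2), Xs),
       ensemble_variance = ev, ou_fit = fit)
}

#' Semi-analytic diffusion prediction versus simulation
#'
#' Runs the full noise-propagation pipeline with zero fitting parameters:
#' (1) simulate the coupled network at rest and measure the MSD of the
#' slow-coordinate X and its drift rate; (2) simulate a single balanced
#' subnetwork at the drive the coupled symmetric fixed point provides, and
#' measure its population activity covariances; (3) invert the
#' linear-response relation for the effective noise covariance; (4)
#' propagate through the slow mode to predict the MSD of X.
#'
#' The decay rate entering the slow-mode propagator is taken from the
#' measured drift (`lambda = "measured"`, the same measurement used to
#' tune the coupling in simulation) or from the mean-field Jacobian
#' (`lambda = "meanfield"`); neither involves fitting to the predicted
#' curve.
#'
#' @param params Coupled-network parameters (stable, near-tuned).
#' @param duration Coupled-run duration (ms); the single-network run is
#'   twice as long (its two independent subnetworks are averaged).
#' @param dt_out Lags for the comparison (ms).
#' @param lambda `"measured"` or `"meanfield"`.
#' @param seed Base seed for the single-network run.
#' @return List with `comparison` (dt, measured MSD, se, predicted),
#'   `lambda_used` (1/ms), `basis`, `C_xi`.
#' @export
semi_analytic_G <- function(params, duration = 30000,
                            dt_out = c(5, 10, 20, 40, 80, 160),
                            lambda = c("measured", "meanfield"),
                            seed = 42L, cm_lag_max = 80) {
  lambda <- match.arg(lambda)
  p <- params
  K <- p$K
  b <- projection_basis(p, K)
  ## coupled network: measured MSD and drift rate of X
  sim <- simulate_network(p, duration = duration, dt_rec = 0.5)
  X <- project(sim$trace, b)
  msd <- msd_curve(X, 0.5, dt_out)
  dd <- drift_diffusion(X, 0.5, X_grid = seq(-0.02, 0.02, by = 0.01),
                        lags = 20, delta = 5e-3)
  lam_meas <- -fit_drift_rate(dd, dt = 20)$lambda # 1/ms, negative
  lam_mf <- b$lambda / p$tau_E
  lam_use <- if (lambda == "measured") lam_meas else lam_mf
  ## single subnetwork at the symmetric-point drive
  E_in <- subnetwork_drive(p, K)
  lin <- single_network_linearization(p, E_in, K)
  p1 <- single_net_params(p$N, K, seed, E_in)
  conn1 <- build_connectivity(p1)
  st1 <- init_state(conn1, p1, mode = "random", m_target = rep(lin$m, 2))
  sim1 <- run_network(st1, conn1, p1, duration = 2 * duration, dt_rec = 0.5)
  sel <- sim1$trace$times > 500
  lags <- seq(-cm_lag_max, cm_lag_max, by = 0.5)
  cm1 <- cm_array(sim1$trace$m[sel, 1], sim1$trace$m[sel, 2], lags, 0.5)
  cm2 <- cm_array(sim1$trace$m[sel, 3], sim1$trace$m[sel, 4], lags, 0.5)
  Cm <- (cm1$Cm + cm2$Cm) / 2
  inv <- noise_correlation_from_cm(Cm, lags, lin$B1, tau_E = p$tau_E)
  th <- theory_cx(inv, b$v0, lam_use, dt_out)
  list(comparison = data.frame(dt = msd$dt, msd = msd$msd, se = msd$se,
                               predicted = th$G_theory),
       lambda_used = lam_use, lambda_measured = lam_meas,
       lambda_meanfield = lam_mf, basis = b, C_xi = inv)
}

exp_nonmirrored <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  N <- N %||% 10000L; K <- K %||% 100L
  p <- desk_network(N, K, seed, mirrored = FALSE)
  r <- resting_X(p, dur = 30000 * scale, dt_rec = 0.5)
  dd <- drift_diffusion(r$X - mean(r$X), 0.5, X_grid = 0,
                        lags = c(5, 10, 20, 40, 80, 160, 320), delta = 5e-3)
  g0 <- dd[!is.na(dd$G), ]
  fit <- fit_ou(g0$dt, g0$G, lambda_init = 1 / 100)
  list(G_curve = g0,
       ou_fit = data.frame(lambda = fit$lambda, D = fit$D),
       offset = data.frame(mean_X = mean(r$X)))
}

exp_sparse_cross <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  N <- N %||% 10000L; K <- K %||% 100L
  p0 <- network_params(N = N, K = K, cross_mode = "sparse",
                       seeds = exp_seeds(seed))
  p0$J_tilde <- detuned_jtilde(p0, K)
  r <- resting_X(p0, dur = 30000 * scale, dt_rec = 0.5)
  dd <- drift_diffusion(r$X, 0.5, X_grid = 0,
                        lags = c(5, 10, 20, 40, 80, 160, 320), delta = 5e-3)
  g0 <- dd[!is.na(dd$G), ]
  fit <- fit_ou(g0$dt, g0$G, lambda_init = 1 / 100)
  list(G_curve = g0, ou_fit = data.frame(J_tilde = p0$J_tilde,
                                         lambda = fit$lambda, D = fit$D))
}

exp_input_noise <- function(scale = 1, N = NULL, K = NULL, seed = 1L) {
  N <- N %||% 10000L; K <- K %||% 100L
  out <- lapply(c(0, 0.01, 0.1), function(sn) {
    p <- if (sn > 0)
      desk_network(N, K, seed, input_noise = list(tau_noise = 30,
                                                  sigma_noise = sn))
    else desk_network(N, K, seed)
    r <- resting_X(p, dur = 20000 * scale, dt_rec = 0.5)
    dd <- drift_diffusion(r$X - mean(r$X), 0.5, X_grid = 0,
                          lags = c(5, 10, 20, 40, 80, 160, 320), delta = 5e-3)
    cbind(sigma_noise = sn, dd[!is.na(dd$G), c("dt", "G", "se_G")])
  })
  list(G_curves = do.call(rbind, out))
}
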