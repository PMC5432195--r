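#' Gaussian tail function and its inverse
#'
#' `gaussian_tail(x)` is the probability that a standard normal variable
#' exceeds `x`; it is the single-neuron transfer function of the mean-field
#' theory: a population with mean input `u` and input variance `alpha` has
#' mean activity `gaussian_tail(-u/sqrt(alpha))`.
#'
#' @param x Numeric vector.
#' @param p Probabilities in (0, 1).
#' @return `gaussian_tail` returns probabilities in (0, 1);
#'   `gaussian_tail_inv` returns the unique `x` with `gaussian_tail(x) = p`.
#' @examples
#' gaussian_tail(0) # 0.5
#' gaussian_tail_inv(gaussian_tail(1.23))
#' @export
gaussian_tail <- function(x) stats::pnorm(x, lower.tail = FALSE)

#' @rdname gaussian_tail
#' @export
gaussian_tail_inv <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("gaussian_tail_inv requires p in (0, 1)")
  stats::qnorm(p, lower.tail = FALSE)
}

#' Population-level input mean and variance
#'
#' Given the four population mean activities, returns the mean input `u`
#' (which includes the `sqrt(K)` scaling of the net synaptic drive and the
#' thresholds) and the input variance `alpha` across neurons of each
#' population. In `"sparse"` cross mode the random cross synapses contribute
#' an extra `J_tilde^2 * m_opp` term to the excitatory input variances; in
#' `"all_to_all"` mode the uniform cross weights are too weak (order
#' `sqrt(K)/N`) to contribute.
#'
#' @param m Length-4 vector of mean activities in \[0, 1\].
#' @param params A [network_params()] object.
#' @param K In-degree to use (defaults to `params$K`; may be `Inf`).
#' @return List with numeric 4-vectors `u` and `alpha`.
#' @export
input_stats <- function(m, params, K = params$K) {
  stopifnot(length(m) == 4L)
  p <- params
  sqrtK <- sqrt(K)
  bracket <- c(m[1] - p$J_E * m[2] - p$J_tilde * m[4] + p$E0,
               m[1] - p$J_I * m[2],
               m[3] - p$J_E * m[4] - p$J_tilde * m[2] + p$E0,
               m[3] - p$J_I * m[4])
  u <- sqrtK * bracket - p$T
  alpha <- c(m[1] + p$J_E^2 * m[2],
             m[1] + p$J_I^2 * m[2],
             m[3] + p$J_E^2 * m[4],
             m[3] + p$J_I^2 * m[4])
  if (p$cross_mode == "sparse") {
    alpha[1] <- alpha[1] + p$J_tilde^2 * m[4]
    alpha[3] <- alpha[3] + p$J_tilde^2 * m[2]
  }
  list(u = u, alpha = alpha, bracket = bracket)
}

#' Mean-field dynamics right-hand side
#'
#' Time derivative of the four population mean activities,
#' `dm_i/dt = (-m_i + H(-u_i/sqrt(alpha_i))) / tau_i`, in 1/ms.
#'
#' @inheritParams input_stats
#' @return Numeric 4-vector `dm/dt` (1/ms).
#' @export
mf_rhs <- function(m, params, K = params$K) {
  st <- input_stats(m, params, K)
  if (any(st$alpha <= 0 & st$u == 0))
    stop("degenerate input: zero variance with zero mean input")
  h <- gaussian_tail(-st$u / sqrt(pmax(st$alpha, .Machine$double.xmin)))
  (-m + h) / pop_tau(params)
}

#' The infinite-K line of balanced states
#'
#' For `J_tilde = J_E - J_I` the infinite-`K` steady-state system is
#' singular and its solutions form a line, parametrized by the activity
#' `x = m_1` of the first excitatory population:
#' `m = (x, x/J_I, -x + J_I*E0/(J_E-J_I), -x/J_I + E0/(J_E-J_I))`.
#' Activities are valid (strictly inside (0,1)) for
#' `0 < x < J_I*E0/(J_E-J_I)`.
#'
#' @param x Position along the line.
#' @param params A [network_params()] object.
#' @return Numeric 4-vector of mean activities.
#' @seealso [line_x_range()], [line_x_symmetric()]
#' @export
line_kinf <- function(x, params) {
  p <- params
  r <- line_x_range(params)
  if (any(x <= r[1] | x >= r[2]))
    stop(sprintf("x must lie in the open interval (0, %g)", r[2]))
  c(x, x / p$J_I,
    -x + p$J_I * p$E0 / (p$J_E - p$J_I),
    -x / p$J_I + p$E0 / (p$J_E - p$J_I))
}

#' @rdname line_kinf
#' @export
line_x_range <- function(params)
  c(0, params$J_I * params$E0 / (params$J_E - params$J_I))

#' @rdname line_kinf
#' @export
line_x_symmetric <- function(params)
  params$J_I * params$E0 / (2 * (params$J_E - params$J_I))

# Partial derivatives f[i, j] = d H(-u_i/sqrt(alpha_i)) / d m_j.
mf_partials <- function(m, params, K = params$K) {
  p <- params
  st <- input_stats(m, params, K)
  u <- st$u
  alpha <- st$alpha
  if (any(alpha <= 0)) stop("partials undefined at zero input variance")
  sqrtK <- sqrt(K)
  Jt <- p$J_tilde
  du <- sqrtK * rbind(c(1, -p$J_E, 0, -Jt),
                      c(1, -p$J_I, 0, 0),
                      c(0, -Jt, 1, -p$J_E),
                      c(0, 0, 1, -p$J_I))
  dalpha <- rbind(c(1, p$J_E^2, 0, 0),
                  c(1, p$J_I^2, 0, 0),
                  c(0, 0, 1, p$J_E^2),
                  c(0, 0, 1, p$J_I^2))
  if (p$cross_mode == "sparse") {
    dalpha[1, 4] <- dalpha[1, 4] + Jt^2
    dalpha[3, 2] <- dalpha[3, 2] + Jt^2
  }
  s <- -u / sqrt(alpha)
  phi <- stats::dnorm(s)
  # d/dm_j H(s_i) = -phi(s_i) ds_i/dm_j; ds/dm = -du/dm/sqrt(a) + u da/dm/(2 a^{3/2})
  f <- phi * (du / sqrt(alpha) - (u / (2 * alpha^1.5)) * dalpha)
  dimnames(f) <- NULL
  f
}

#' Solve the finite-K mean-field fixed point
#'
#' Solves the four steady-state equations `m_i = H(-u_i/sqrt(alpha_i))` by a
#' damped Newton iteration with analytic Jacobian. The symmetric solution
#' (`m1 = m3`, `m2 = m4`), which always exists, is found in the reduced
#' two-variable subspace when `symmetric = TRUE`. The default initial guess
#' is the symmetric point of the infinite-`K` line.
#'
#' @param params A [network_params()] object.
#' @param guess Optional initial guess (length 4, or length 2 as
#'   `(m_E, m_I)` when `symmetric`).
#' @param K In-degree (defaults to `params$K`).
#' @param symmetric Solve in the symmetric subspace (default `TRUE`).
#' @param tol Residual tolerance (max absolute steady-state residual).
#' @param max_iter Maximum Newton iterations.
#' @return A `"mf_point"`: list with `m`, `u`, `alpha`, `residual`, `K`.
#' @export
solve_fixed_point <- function(params, guess = NULL, K = params$K,
                              symmetric = TRUE, tol = 1e-12,
                              max_iter = 200L) {
  if (is.null(guess)) {
    m0 <- line_kinf(line_x_symmetric(params), params_on_line(params))
    guess <- if (symmetric) m0[1:2] else m0
  }
  if (symmetric && length(guess) == 4L) guess <- guess[1:2]
  expand <- function(v) if (symmetric) c(v, v) else v
  resid <- function(v) {
    m <- expand(v)
    st <- input_stats(m, params, K)
    r <- m - gaussian_tail(-st$u / sqrt(st$alpha))
    if (symmetric) r[1:2] else r
  }
  jac <- function(v) {
    m <- expand(v)
    f <- mf_partials(m, params, K)
    if (symmetric) {
      # collapse columns (m1, m3) and (m2, m4) of the 4x4 system
      J <- cbind(f[1:2, 1] + f[1:2, 3], f[1:2, 2] + f[1:2, 4])
      diag(2) - J
    } else diag(4) - f
  }
  v <- pmin(pmax(guess, 1e-10), 1 - 1e-10)
  r <- resid(v)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    step <- tryCatch(solve(jac(v), r), error = function(e) r) # fallback: damped fixed-point step
    lam <- 1
    repeat {
      vn <- pmin(pmax(v - lam * step, 1e-12), 1 - 1e-12)
      rn <- resid(vn)
      if (max(abs(rn)) < max(abs(r)) || lam < 1e-6) break
      lam <- lam / 2
    }
    v <- vn
    r <- rn
  }
  if (max(abs(r)) >= tol)
    stop(sprintf("fixed-point solver did not converge: residual %.3e", max(abs(r))))
  m <- expand(v)
  if (any(m < 1e-9 | m > 1 - 1e-9))
    stop("fixed point saturates at 0 or 1; parameters outside the balanced regime")
  st <- input_stats(m, params, K)
  structure(list(m = m, u = st$u, alpha = st$alpha,
                 residual = max(abs(r)), K = K),
            class = "mf_point")
}

# same params but with J_tilde replaced by J_E - J_I so the line exists
params_on_line <- function(params) {
  params$J_tilde <- params$J_E - params$J_I
  params
}

#' Linearized mean-field dynamics at a point
#'
#' Computes the matrix of partials `f[i, j]` of the transfer function with
#' respect to the mean activities, and assembles the Jacobian of the
#' mean-field dynamics with time measured in units of `tau_E` (inhibitory
#' rows are divided by `tau = tau_I/tau_E`). At a symmetric point the four
#' eigenvalues are also available in closed form (see
#' [symmetric_eigenvalues()]); `lambda0` is the eigenvalue with real part
#' closest to zero.
#'
#' @param point An `"mf_point"` from [solve_fixed_point()], or a length-4
#'   activity vector.
#' @param params A [network_params()] object.
#' @param K In-degree (defaults to `point$K` or `params$K`).
#' @return A `"jacobian_info"`: list with `f` (4x4), `A` (4x4, units
#'   1/tau_E), `eigenvalues` (complex, sorted by |Re|), `lambda0`, `tau`,
#'   and `closed_form` (at symmetric points, the four sign combinations of
#'   the closed-form expression, named `pp`, `pm`, `mp`, `mm` with the first
#'   letter the outer and the second the inner sign).
#' @export
jacobian <- function(point, params, K = NULL) {
  m <- if (inherits(point, "mf_point")) point$m else point
  if (is.null(K)) K <- if (inherits(point, "mf_point")) point$K else params$K
  if (any(m <= 0 | m >= 1)) stop("Jacobian undefined on the boundary of [0,1]^4")
  f <- mf_partials(m, params, K)
  tau <- params$tau_I / params$tau_E
  scale <- c(1, tau, 1, tau)
  A <- (f - diag(4)) / scale
  ev <- eigen(A, only.values = TRUE)$values
  ev <- ev[order(abs(Re(ev)))]
  symmetric <- abs(m[1] - m[3]) < 1e-10 && abs(m[2] - m[4]) < 1e-10
  cf <- if (symmetric) symmetric_eigenvalues(f, tau) else NULL
  structure(list(f = f, A = A, eigenvalues = ev, lambda0 = ev[1],
                 tau = tau, closed_form = cf),
            class = "jacobian_info")
}

#' Closed-form eigenvalues at a symmetric fixed point
#'
#' At a symmetric point the Jacobian has the block form `[[P, Q], [Q, P]]`,
#' and its eigenvalues split into those of `P + Q` and `P - Q`:
#' `lambda = (a + d)/2 +/- sqrt((a - d)^2 + (4/tau) f21 (f12 +/- f14))/2`
#' with `a = f11 - 1`, `d = (f22 - 1)/tau`. The inner sign `+` selects the
#' symmetric (`P + Q`) pair and `-` the antisymmetric (`P - Q`) pair; the
#' antisymmetric pair contains the slow mode that vanishes at the tuned
#' coupling (for the standard parameter set, its `pm` member).
#'
#' @param f 4x4 matrix of partials (from a symmetric point).
#' @param tau Ratio `tau_I/tau_E`.
#' @return Named complex vector `c(pp, pm, mp, mm)`.
#' @export
symmetric_eigenvalues <- function(f, tau) {
  a <- f[1, 1] - 1
  d <- (f[2, 2] - 1) / tau
  out <- c()
  for (inner in c(1, -1)) {
    disc <- as.complex((a - d)^2 + (4 / tau) * f[2, 1] * (f[1, 2] + inner * f[1, 4]))
    for (outer in c(1, -1)) {
      lab <- paste0(ifelse(outer > 0, "p", "m"), ifelse(inner > 0, "p", "m"))
      out[lab] <- (a + d) / 2 + outer * sqrt(disc) / 2
    }
  }
  out[c("pp", "pm", "mp", "mm")]
}

# Eigenvalue (real part, closest to zero) of the antisymmetric block
# P - Q = [[f11-1, f12-f14], [f21/tau, (f22-1)/tau]] at the symmetric fixed
# point, as a function of J_tilde. This is the mode that vanishes at the
# tuned coupling. Units: 1/tau_E.
lambda_slow <- function(params, K = params$K, J_tilde = params$J_tilde,
                        guess = NULL) {
  params$J_tilde <- J_tilde
  fp <- solve_fixed_point(params, guess = guess, K = K)
  f <- mf_partials(fp$m, params, K)
  tau <- params$tau_I / params$tau_E
  PmQ <- rbind(c(f[1, 1] - 1, f[1, 2] - f[1, 4]),
               c(f[2, 1] / tau, (f[2, 2] - 1) / tau))
  ev <- Re(eigen(PmQ, only.values = TRUE)$values)
  ev[which.min(abs(ev))]
}

#' Tune the mutual inhibition for a line of balanced states
#'
#' For infinite `K` the tuned coupling is exactly `J_E - J_I`. For finite
#' `K` the coupling at which the slow eigenvalue of the symmetric fixed
#' point vanishes is found by root finding on the closed-form eigenvalue
#' over the bracket `[J_E - J_I, J_E - J_I + 1]`.
#'
#' @param params A [network_params()] object.
#' @param K In-degree (defaults to `params$K`; may be `Inf`).
#' @param tol Root tolerance on `J_tilde`.
#' @return The tuned coupling `J_tilde*` (scalar).
#' @examples
#' p <- network_params(N = 2000, K = 1000)
#' tune_jtilde(p, K = Inf) # exactly J_E - J_I = 1.5
#' @export
tune_jtilde <- function(params, K = params$K, tol = 1e-10) {
  if (is.infinite(K)) return(params$J_E - params$J_I)
  lo <- params$J_E - params$J_I
  fn <- function(jt) lambda_slow(params, K, jt)
  flo <- fn(lo + 1e-9)
  # the zero crossing sits close above J_E - J_I at large K but moves up as
  # K decreases (and further in sparse cross mode); widen the bracket as
  # needed while the symmetric fixed point still exists
  hi <- lo + 1
  fhi <- fn(hi)
  while (flo * fhi > 0 && hi < lo + 2.5) {
    hi <- hi + 0.5
    fhi <- tryCatch(fn(hi), error = function(e) NA_real_)
    if (is.na(fhi)) stop("fixed point lost before the slow eigenvalue crossed zero")
  }
  if (flo * fhi > 0)
    stop("no sign change of the slow eigenvalue above J_E - J_I")
  stats::uniroot(fn, c(lo + 1e-9, hi), f.lower = flo, f.upper = fhi,
                 tol = tol)$root
}

#' Slow and next eigenvalue as a function of the mutual inhibition
#'
#' Evaluates the eigenvalue closest to zero (the slow antisymmetric mode)
#' and the real part of the next eigenvalue at the symmetric fixed point,
#' over a grid of coupling values.
#'
#' @param params A [network_params()] object.
#' @param K In-degree.
#' @param jt_grid Numeric vector of `J_tilde` values.
#' @return Data frame with columns `J_tilde`, `lambda` (slow mode, 1/tau_E),
#'   `lambda_next` (real part of the next-closest eigenvalue).
#' @export
lambda_vs_jtilde <- function(params, K = params$K, jt_grid) {
  rows <- lapply(jt_grid, function(jt) {
    params$J_tilde <- jt
    fp <- solve_fixed_point(params, K = K)
    J <- jacobian(fp, params, K)
    ev <- J$eigenvalues
    data.frame(J_tilde = jt, lambda = lambda_slow(params, K, jt),
               lambda_next = Re(ev[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Projection basis along the approximate attractor
#'
#' Returns the symmetric fixed point `m0`, the slow eigenvalue `lambda`, the
#' right eigenvector `r0` rescaled so that its first component is 1
#' (matching the infinite-`K` null direction `(1, 1/J_I, -1, -1/J_I)`), and
#' the left eigenvector `v0` normalized so `v0 . r0 = 1`. The scalar
#' coordinate along the attractor is `X(t) = v0 . (m(t) - m0)`. The
#' remaining left eigenvectors are returned (rows of `V_perp`) for
#' perpendicular projections.
#'
#' For `K = Inf` the basis is computed from the singular infinite-`K` linear
#' system: `r0` is its exact null vector and `v0` the left null vector of
#' the mean-field Jacobian, obtained by rescaling the left null vector of
#' the linear system by the (analytic) per-population linearization gains.
#'
#' @param params A [network_params()] object (tuned or near-tuned).
#' @param K In-degree (defaults to `params$K`; may be `Inf`).
#' @return A `"projection_basis"`: list with `m0`, `v0`, `r0`, `lambda`,
#'   `V_perp`.
#' @export
projection_basis <- function(params, K = params$K) {
  p <- params
  r_pattern <- c(1, 1 / p$J_I, -1, -1 / p$J_I)
  if (is.infinite(K)) {
    pl <- params_on_line(p)
    m0 <- line_kinf(line_x_symmetric(pl), pl)
    M <- rbind(c(1, -p$J_E, 0, -pl$J_tilde),
               c(1, -p$J_I, 0, 0),
               c(0, -pl$J_tilde, 1, -p$J_E),
               c(0, 0, 1, -p$J_I))
    # dynamics linearization: A = -diag(c) %*% M with gains
    # c_i = phi(s_i) * sqrt(K) / (tau_i sqrt(alpha_i)); sqrt(K) drops out of
    # the normalized left null vector.
    sv <- svd(M)
    w <- sv$u[, 4] # left null vector of M
    st <- input_stats(m0, pl, K = 1) # alpha only
    s <- gaussian_tail_inv(m0)
    gain <- stats::dnorm(s) / (pop_tau(p) / p$tau_E) / sqrt(st$alpha)
    v0 <- w / gain
    v0 <- v0 / sum(v0 * r_pattern)
    return(structure(list(m0 = m0, v0 = v0, r0 = r_pattern, lambda = 0,
                          V_perp = NULL, K = K),
                     class = "projection_basis"))
  }
  fp <- solve_fixed_point(p, K = K)
  J <- jacobian(fp, p, K)
  er <- eigen(J$A)
  el <- eigen(t(J$A))
  i_r <- which.min(abs(Re(er$values)))
  lambda <- er$values[i_r]
  if (abs(Im(lambda)) > 1e-8 * max(1, abs(Re(lambda))))
    stop("slow eigenvalue is complex; no one-dimensional slow direction")
  lambda <- Re(lambda)
  r0 <- Re(er$vectors[, i_r])
  r0 <- r0 / r0[1]
  i_l <- which.min(abs(el$values - lambda))
  v0 <- Re(el$vectors[, i_l])
  v0 <- v0 / sum(v0 * r0)
  V_perp <- t(Re(el$vectors[, -i_l, drop = FALSE]))
  structure(list(m0 = fp$m, v0 = v0, r0 = r0, lambda = lambda,
                 V_perp = V_perp, K = K),
            class = "projection_basis")
}

#' Integrate the (noisy) mean-field equations
#'
#' Euler-Maruyama integration of the mean-field dynamics with optional
#' per-population independent white noise of intensity `sigma^2` added
#' inside the population equations (`tau_i dm_i = (-m_i + H_i) dt + sigma
#' dW_i`). Activities are clipped to \[0, 1\] after each step; the step is
#' declared unstable if the unclipped state leaves \[-0.1, 1.1\].
#'
#' @param m_init Length-4 initial activities in (0, 1).
#' @param params A [network_params()] object.
#' @param duration Integration time (ms).
#' @param noise_sigma Noise intensity `sigma` (units activity * sqrt(ms));
#'   0 gives the deterministic dynamics.
#' @param dt Time step (ms).
#' @param dt_rec Recording interval (ms); defaults to `dt`.
#' @param K In-degree (defaults to `params$K`).
#' @return A `"population_trace"`: list with `times` (ms) and `m`
#'   (matrix, one column per population).
#' @export
integrate_mf <- function(m_init, params, duration, noise_sigma = 0,
                         dt = 0.1, dt_rec = dt, K = params$K) {
  stopifnot(length(m_init) == 4L, all(m_init > 0 & m_init < 1), duration > 0)
  tau <- pop_tau(params)
  n_steps <- ceiling(duration / dt)
  every <- max(1L, round(dt_rec / dt))
  n_rec <- floor(n_steps / every)
  out <- matrix(NA_real_, n_rec, 4)
  m <- m_init
  sq <- noise_sigma * sqrt(dt)
  k <- 0L
  for (i in seq_len(n_steps)) {
    dm <- mf_rhs(m, params, K) * dt
    if (noise_sigma > 0) dm <- dm + sq * stats::rnorm(4) / tau
    m <- m + dm
    if (any(m < -0.1 | m > 1.1))
      stop("mean-field integration unstable: reduce dt")
    m <- pmin(pmax(m, 0), 1)
    if (i %% every == 0L) {
      k <- k + 1L
      out[k, ] <- m
    }
  }
  population_trace(times = seq_len(n_rec) * every * dt, m = out)
}

#' Nullclines of the reduced dynamics in the m1-m3 plane
#'
#' Eliminates the fast inhibitory variables through their steady-state
#' equations (`m2` is a function of `m1`, and `m4` of `m3`) and solves, for
#' each `m1` on the grid, the `m3` on the excitatory steady-state manifold
#' of each subnetwork: the `dm1/dt = 0` and `dm3/dt = 0` curves projected on
#' the plane. Grid points where no root is bracketed are returned as `NA`.
#'
#' @param params A [network_params()] object.
#' @param K In-degree (finite).
#' @param m1_grid Grid of `m1` values in (0, 1).
#' @return Data frame with columns `m1`, `m3_null1` (the `dm1/dt = 0`
#'   curve), `m3_null3` (the `dm3/dt = 0` curve).
#' @export
nullclines <- function(params, K = params$K, m1_grid) {
  stopifnot(is.finite(K))
  m3_of <- function(m1, which_eq) {
    m2 <- solve_inhibitory(m1, params, K)
    res <- function(m3) {
      m4 <- solve_inhibitory(m3, params, K)
      st <- input_stats(c(m1, m2, m3, m4), params, K)
      i <- if (which_eq == 1L) 1L else 3L
      mi <- if (which_eq == 1L) m1 else m3
      mi - gaussian_tail(-st$u[i] / sqrt(st$alpha[i]))
    }
    lo <- 1e-8
    hi <- 1 - 1e-8
    flo <- res(lo)
    fhi <- res(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
    stats::uniroot(res, c(lo, hi), f.lower = flo, f.upper = fhi,
                   tol = 1e-12)$root
  }
  data.frame(
    m1 = m1_grid,
    m3_null1 = vapply(m1_grid, m3_of, numeric(1), which_eq = 1L),
    m3_null3 = vapply(m1_grid, m3_of, numeric(1), which_eq = 3L)
  )
}

# steady-state inhibitory activity of one subnetwork given its excitatory
# activity (the inhibitory equation does not involve the other subnetwork)
solve_inhibitory <- function(mE, params, K = params$K) {
  p <- params
  res <- function(mI) {
    u <- sqrt(K) * (mE - p$J_I * mI) - p$T[2]
    a <- mE + p$J_I^2 * mI
    mI - gaussian_tail(-u / sqrt(a))
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  flo <- res(lo); fhi <- res(hi)
  # saturated subnetwork: the root degenerates onto the boundary
  if (flo > 0 && fhi > 0) return(lo)
  if (flo < 0 && fhi < 0) return(hi)
  stats::uniroot(res, c(lo, hi), f.lower = flo, f.upper = fhi,
                 tol = 1e-14)$root
}

#' Slope of the excitatory nullcline at a symmetric point (closed form)
#'
#' The derivative `dm1/dm3` along the `dm1/dt = 0` manifold (with the
#' inhibitory variables eliminated), expressed in terms of the partials at
#' the symmetric fixed point:
#' `dm1/dm3 = f14 f21 / (f11 f22 - f12 f21 + 1 - f11 - f22)`.
#' The tuning condition is `dm1/dm3 = -1`, equivalent to a vanishing slow
#' eigenvalue.
#'
#' @param f 4x4 matrix of partials at a symmetric point.
#' @return Scalar slope `dm1/dm3`.
#' @export
nullcline_slope <- function(f) {
  f[1, 4] * f[2, 1] /
    (f[1, 1] * f[2, 2] - f[1, 2] * f[2, 1] + 1 - (f[1, 1] + f[2, 2]))
}

#' Cross-partial that makes the slow eigenvalue vanish
#'
#' Solving the tuning condition for the cross-coupling partial gives
#' `f14 = (f12 f21 - 1 + f11 + f22 - f11 f22) / f21`; substituting this
#' value into the closed-form eigenvalues makes one eigenvalue of the
#' antisymmetric pair exactly zero.
#'
#' @param f 4x4 matrix of partials at a symmetric point.
#' @return The value of `f[1, 4]` at tuning.
#' @export
tuned_f14 <- function(f) {
  (f[1, 2] * f[2, 1] - 1 + f[1, 1] + f[2, 2] - f[1, 1] * f[2, 2]) / f[2, 1]
}
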