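#' Linearized dynamics of a single balanced subnetwork
#'
#' Solves the two-population (excitatory/inhibitory) mean-field fixed point
#' of one balanced subnetwork receiving constant excitatory drive `E_in`,
#' and linearizes around it. `B1` is the 2x2 response to mean-activity
#' perturbations (time in units of `tau_E`, inhibitory row divided by
#' `tau = tau_I/tau_E`); `B2` is the response to perturbations of the
#' feedforward drive — only the excitatory population receives external
#' drive, so the inhibitory-channel column is zero.
#'
#' In the coupled architecture `E_in` is the mean drive at the symmetric
#' fixed point, `E0 - J_tilde * m_I`; [subnetwork_drive()] computes it.
#'
#' @param params A [network_params()] object.
#' @param E_in Feedforward drive to the excitatory population.
#' @param K In-degree (defaults to `params$K`).
#' @return List with `B1`, `B2` (2x2 matrices, units 1/tau_E), `m` (the
#'   2-population fixed point), `u`, `alpha`, `E_in`.
#' @export
single_network_linearization <- function(params, E_in, K = params$K) {
  p <- params
  tau <- p$tau_I / p$tau_E
  sqrtK <- sqrt(K)
  stats2 <- function(m) {
    u <- c(sqrtK * (m[1] - p$J_E * m[2] + E_in) - p$T[1],
           sqrtK * (m[1] - p$J_I * m[2]) - p$T[2])
    a <- c(m[1] + p$J_E^2 * m[2], m[1] + p$J_I^2 * m[2])
    list(u = u, alpha = a)
  }
  resid <- function(m) {
    st <- stats2(m)
    m - gaussian_tail(-st$u / sqrt(st$alpha))
  }
  partials2 <- function(m) {
    st <- stats2(m)
    du <- sqrtK * rbind(c(1, -p$J_E), c(1, -p$J_I))
    da <- rbind(c(1, p$J_E^2), c(1, p$J_I^2))
    s <- -st$u / sqrt(st$alpha)
    stats::dnorm(s) * (du / sqrt(st$alpha) -
                       (st$u / (2 * st$alpha^1.5)) * da)
  }
  m <- c(0.25, 0.1)
  r <- resid(m)
  for (it in 1:200) {
    if (max(abs(r)) < 1e-13) break
    step <- solve(diag(2) - partials2(m), r)
    lam <- 1
    repeat {
      mn <- pmin(pmax(m - lam * step, 1e-12), 1 - 1e-12)
      rn <- resid(mn)
      if (max(abs(rn)) < max(abs(r)) || lam < 1e-6) break
      lam <- lam / 2
    }
    m <- mn; r <- rn
  }
  if (max(abs(r)) > 1e-10)
    stop("single-network fixed point did not converge")
  if (any(m < 1e-9 | m > 1 - 1e-9))
    stop("single-network fixed point saturates at 0 or 1")
  st <- stats2(m)
  f <- partials2(m)
  B1 <- (f - diag(2)) / c(1, tau)
  phi1 <- stats::dnorm(-st$u[1] / sqrt(st$alpha[1]))
  B2 <- rbind(c(phi1 * sqrtK / sqrt(st$alpha[1]), 0), c(0, 0))
  list(B1 = B1, B2 = B2, m = m, u = st$u, alpha = st$alpha, E_in = E_in)
}

#' Mean drive to one subnetwork at the symmetric fixed point
#'
#' @param params A [network_params()] object.
#' @param K In-degree.
#' @return `E0 - J_tilde * m_I` evaluated at the symmetric fixed point.
#' @export
subnetwork_drive <- function(params, K = params$K) {
  fp <- solve_fixed_point(params, K = K)
  params$E0 - params$J_tilde * fp$m[4]
}

#' Effective noise covariance from measured activity covariances
#'
#' Inverts the linear-response relation for a subnetwork driven by
#' stationary noise, `dm/dt = B1 dm + xi`: with the activity covariance
#' `C(t) = <dm(s+t) dm(s)^T>` the noise covariance is
#' `C_xi(t) = -C'' - C' B1^T + B1 C' + B1 C B1^T`.
#' Derivatives are central finite differences after Gaussian smoothing
#' (empirical second derivatives are otherwise dominated by sampling
#' noise).
#'
#' @param Cm Array `length(lag) x 2 x 2`: the measured covariance of the
#'   two population activities, on a uniform, symmetric lag grid (time in
#'   ms; element `[l, i, j]` is `cov(m_i(t + lag_l), m_j(t))`).
#' @param lag Lag grid (ms), symmetric around 0, uniform spacing at most
#'   `tau_E/5`.
#' @param B1 Single-subnetwork Jacobian (units 1/tau_E; converted
#'   internally to 1/ms with `tau_E`).
#' @param tau_E Excitatory time constant (ms).
#' @param smooth_sd Gaussian smoothing width (ms; default `tau_E/5`).
#' @return List with `lag` (trimmed grid) and `C_xi` (array, same layout).
#' @export
noise_correlation_from_cm <- function(Cm, lag, B1, tau_E = 10,
                                      smooth_sd = tau_E / 5) {
  h <- lag[2] - lag[1]
  if (h > tau_E / 5 + 1e-9)
    stop("lag grid too coarse: need spacing <= tau_E/5")
  B <- B1 / tau_E # 1/ms units
  n <- length(lag)
  sm <- function(v) gauss_smooth(v, h, smooth_sd)
  S <- Cm
  for (i in 1:2) for (j in 1:2) S[, i, j] <- sm(Cm[, i, j])
  d1 <- S; d2 <- S
  for (i in 1:2) for (j in 1:2) {
    d1[, i, j] <- central_diff(S[, i, j], h, order = 1)
    d2[, i, j] <- central_diff(S[, i, j], h, order = 2)
  }
  keep <- 2:(n - 1)
  C_xi <- array(NA_real_, c(length(keep), 2, 2))
  for (il in seq_along(keep)) {
    l <- keep[il]
    C <- S[l, , ]; C1 <- d1[l, , ]; C2 <- d2[l, , ]
    C_xi[il, , ] <- -C2 - C1 %*% t(B) + B %*% C1 + B %*% C %*% t(B)
  }
  list(lag = lag[keep], C_xi = C_xi)
}

gauss_smooth <- function(v, h, sd) {
  if (sd <= 0) return(v)
  half <- max(1L, ceiling(3 * sd / h))
  k <- stats::dnorm(seq(-half, half) * h, sd = sd)
  k <- k / sum(k)
  n <- length(v)
  vp <- c(rep(v[1], half), v, rep(v[n], half))
  stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
}

central_diff <- function(v, h, order = 1) {
  n <- length(v)
  out <- rep(NA_real_, n)
  if (order == 1) out[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  else out[2:(n - 1)] <- (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) / h^2
  out[1] <- out[2]; out[n] <- out[n - 1]
  out
}

#' Predicted autocovariance and diffusion of the slow coordinate
#'
#' Propagates the subnetwork noise covariance through the slow mode: with
#' the block-diagonal 4-population noise covariance `C~_xi` (the two
#' subnetworks' noise is independent), the slow-coordinate dynamics are
#' `dX/dt = lambda X + v0 . xi`, so by the Wiener-Khinchin relation
#' `C_X(t) = -(1/2 lambda) Int e^(lambda |t'|) v0^T C~_xi(t - t') v0 dt'`
#' and `G_theory(dt) = 2 (C_X(0) - C_X(dt))`. The integral is evaluated by
#' the trapezoidal rule over the measured support of `C_xi` (zero beyond).
#'
#' @param C_xi List from [noise_correlation_from_cm()] (2x2 covariance on
#'   its lag grid, in 1/ms^2 units of the activity dynamics).
#' @param v0 Slow left eigenvector (length 4).
#' @param lambda Slow eigenvalue in 1/ms (must be negative).
#' @param dt_out Lags at which to report `C_X` and `G_theory` (ms).
#' @return A `"theory_G"`: data frame with `dt`, `C_X`, `G_theory`.
#' @export
theory_cx <- function(C_xi, v0, lambda, dt_out) {
  if (lambda >= 0) stop("lambda must be negative (stable slow mode)")
  lagx <- C_xi$lag
  h <- lagx[2] - lagx[1]
  # scalar projection s(t) = v0^T Ctilde_xi(t) v0 with block structure
  va <- v0[1:2]; vb <- v0[3:4]
  s <- vapply(seq_along(lagx), function(l) {
    Cl <- C_xi$C_xi[l, , ]
    drop(t(va) %*% Cl %*% va + t(vb) %*% Cl %*% vb)
  }, numeric(1))
  trap_w <- rep(h, length(lagx)); trap_w[c(1, length(lagx))] <- h / 2
  cx_at <- function(t0) {
    # integrand e^(lambda|t'|) s(t0 - t') over t' in [t0 - L, t0 + L]
    tp <- t0 - lagx # s support maps to these t' values
    -(1 / (2 * lambda)) * sum(exp(lambda * abs(tp)) * s * trap_w)
  }
  C0 <- cx_at(0)
  CX <- vapply(dt_out, cx_at, numeric(1))
  out <- data.frame(dt = dt_out, C_X = CX, G_theory = 2 * (C0 - CX))
  class(out) <- c("theory_G", "data.frame")
  out
}

#' Covariance array of a two-population trace
#'
#' Convenience wrapper building the `length(lag) x 2 x 2` covariance array
#' required by [noise_correlation_from_cm()] from two activity series,
#' using [population_cross_covariance()] for every ordered pair.
#'
#' @param mE,mI Excitatory and inhibitory mean-activity series.
#' @param lags Symmetric lag grid (ms).
#' @param dt_samp Sampling interval (ms).
#' @return List with `lag` and `Cm` (array `[lag, i, j]` =
#'   `cov(m_i(t+lag), m_j(t))`).
#' @export
cm_array <- function(mE, mI, lags, dt_samp) {
  series <- list(mE, mI)
  Cm <- array(NA_real_, c(length(lags), 2, 2))
  for (i in 1:2) for (j in 1:2)
    Cm[, i, j] <- population_cross_covariance(series[[i]], series[[j]],
                                              lags, dt_samp)$C
  list(lag = lags, Cm = Cm)
}
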