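#' Project a population trace onto the slow direction
#'
#' The scalar coordinate along the approximate attractor is
#' `X(t) = v0 . (m(t) - m0)` with `v0` the slow left eigenvector and `m0`
#' the symmetric fixed point. With `perpendicular = TRUE` the projections
#' on the remaining left eigenvectors are returned as well.
#'
#' @param trace A `"population_trace"`.
#' @param basis A [projection_basis()] object.
#' @param perpendicular Also return the perpendicular projections.
#' @return Numeric vector `X` (with attribute `times`), or a data frame
#'   with columns `time`, `X`, `P1`..`P3` when `perpendicular`.
#' @export
project <- function(trace, basis, perpendicular = FALSE) {
  dm <- sweep(trace$m, 2, basis$m0)
  X <- as.vector(dm %*% basis$v0)
  if (!perpendicular) {
    attr(X, "times") <- trace$times
    return(X)
  }
  if (is.null(basis$V_perp)) stop("basis has no perpendicular eigenvectors")
  P <- dm %*% t(basis$V_perp)
  colnames(P) <- paste0("P", seq_len(ncol(P)))
  data.frame(time = trace$times, X = X, P)
}

#' Conditional drift and diffusion moments along the attractor
#'
#' Implements the binning estimator of the conditional moments
#' `F(X, dt) = <X(t+dt) - X(t) | X(t) = X>` and
#' `G(X, dt) = <(X(t+dt) - X(t))^2 | X(t) = X>`: all sample times with
#' `|X(t) - X| < delta` qualify, displacements are averaged over qualifying
#' times and over trials.
#'
#' @param X A numeric trace of positions (uniform sampling), or a list of
#'   such traces (independent trials).
#' @param dt_samp Sampling interval of the traces (ms).
#' @param X_grid Conditioning positions.
#' @param lags Lag times `dt` (ms); rounded to multiples of `dt_samp`.
#' @param delta Conditioning half-width.
#' @param min_count Cells with fewer qualifying samples are reported as
#'   `NA` (flagged, never zero).
#' @return A `"drift_diffusion"` data frame with columns `X`, `dt`, `F`,
#'   `G`, `count`, `se_F`, `se_G`.
#' @export
drift_diffusion <- function(X, dt_samp, X_grid, lags, delta = 1e-3,
                            min_count = 50L) {
  if (!is.list(X)) X <- list(X)
  lag_s <- unique(pmax(1L, as.integer(round(lags / dt_samp))))
  nX <- length(X_grid)
  nL <- length(lag_s)
  cnt <- s1 <- s2 <- s4 <- matrix(0, nX, nL)
  max_lag <- max(lag_s)
  for (x_tr in X) {
    n <- length(x_tr)
    if (n <= max_lag) next
    for (ix in seq_len(nX)) {
      idx <- which(abs(x_tr - X_grid[ix]) < delta)
      idx <- idx[idx <= n - max_lag]
      if (!length(idx)) next
      for (il in seq_len(nL)) {
        d <- x_tr[idx + lag_s[il]] - x_tr[idx]
        cnt[ix, il] <- cnt[ix, il] + length(d)
        s1[ix, il] <- s1[ix, il] + sum(d)
        s2[ix, il] <- s2[ix, il] + sum(d^2)
        s4[ix, il] <- s4[ix, il] + sum(d^4)
      }
    }
  }
  Fm <- ifelse(cnt >= min_count, s1 / cnt, NA_real_)
  Gm <- ifelse(cnt >= min_count, s2 / cnt, NA_real_)
  var_d <- pmax(s2 / pmax(cnt, 1) - Fm^2, 0)
  var_d2 <- pmax(s4 / pmax(cnt, 1) - Gm^2, 0)
  out <- data.frame(
    X = rep(X_grid, nL), dt = rep(lag_s * dt_samp, each = nX),
    F = as.vector(Fm), G = as.vector(Gm), count = as.vector(cnt),
    se_F = as.vector(sqrt(var_d / pmax(cnt, 1))),
    se_G = as.vector(sqrt(var_d2 / pmax(cnt, 1))))
  class(out) <- c("drift_diffusion", "data.frame")
  out
}

#' Unconditional mean squared displacement
#'
#' The stationary mean squared displacement
#' `MSD(dt) = <(X(t+dt) - X(t))^2>` over all sample times (no conditioning
#' on the starting position). This is the quantity the semi-analytic
#' diffusion prediction ([theory_cx()]) computes; unlike the conditioned
#' `G(X = 0, dt)` it saturates at twice the stationary variance.
#'
#' @param X Numeric trace or list of traces (uniform sampling).
#' @param dt_samp Sampling interval (ms).
#' @param lags Lags (ms).
#' @return Data frame with `dt`, `msd`, `se`, `count`.
#' @export
msd_curve <- function(X, dt_samp, lags) {
  if (!is.list(X)) X <- list(X)
  lag_s <- unique(pmax(1L, as.integer(round(lags / dt_samp))))
  cnt <- s2 <- s4 <- numeric(length(lag_s))
  for (x_tr in X) {
    n <- length(x_tr)
    for (il in seq_along(lag_s)) {
      L <- lag_s[il]
      if (n <= L) next
      d2 <- (x_tr[(1 + L):n] - x_tr[1:(n - L)])^2
      cnt[il] <- cnt[il] + length(d2)
      s2[il] <- s2[il] + sum(d2)
      s4[il] <- s4[il] + sum(d2^2)
    }
  }
  m <- s2 / cnt
  v <- pmax(s4 / cnt - m^2, 0)
  # effective sample size: displacements decorrelate over about one lag
  n_eff <- pmax(cnt * dt_samp / (lag_s * dt_samp), 4)
  data.frame(dt = lag_s * dt_samp, msd = m, se = sqrt(v / n_eff),
             count = cnt)
}

#' Drift rate from the conditional mean displacement
#'
#' Fits `F(X, dt)` at the smallest lag to the Ornstein-Uhlenbeck form
#' `F = X (exp(-lambda dt) - 1)` by linear regression of `F` on `X`,
#' returning the decay rate `lambda` (positive for restoring drift).
#'
#' @param dd A [drift_diffusion()] estimate.
#' @param dt Lag to use (ms; default the smallest available).
#' @return List with `lambda` (1/ms), `slope`, `se_slope`.
#' @export
fit_drift_rate <- function(dd, dt = min(dd$dt)) {
  d <- dd[dd$dt == dt & !is.na(dd$F), ]
  if (nrow(d) < 3) stop("need at least 3 populated X cells")
  fit <- stats::lm(F ~ X, data = d, weights = d$count)
  slope <- unname(stats::coef(fit)["X"])
  if (slope <= -1) slope <- -1 + 1e-10
  list(lambda = -log1p(slope) / dt, slope = slope,
       se_slope = summary(fit)$coefficients["X", "Std. Error"])
}

#' Ornstein-Uhlenbeck process helpers
#'
#' `ou_G(dt, lambda, D)` is the mean squared displacement over lag `dt`
#' conditioned on starting at the fixed point,
#' `(D/lambda)(1 - exp(-2 lambda dt))` — the form the conditional binning
#' estimator of `G(X = 0, dt)` measures. (The unconditional stationary
#' MSD is `(2D/lambda)(1 - exp(-lambda dt))`; both grow as `2 D dt` for
#' small lags.) `ou_variance(t, lambda, D)` is the variance of an ensemble
#' released from a common point, identical in form. `simulate_ou` draws a
#' path with the exact discrete-time transition. `lambda > 0` is the decay
#' rate.
#'
#' @param dt,t Time (ms).
#' @param lambda Decay rate (1/ms).
#' @param D Diffusion coefficient (X^2/ms).
#' @param n Number of samples.
#' @param dt_samp Sampling interval (ms).
#' @param X0 Initial value.
#' @return Numeric vector.
#' @export
ou_G <- function(dt, lambda, D) (D / lambda) * (1 - exp(-2 * lambda * dt))

#' @rdname ou_G
#' @export
ou_variance <- function(t, lambda, D) (D / lambda) * (1 - exp(-2 * lambda * t))

#' @rdname ou_G
#' @export
simulate_ou <- function(n, dt_samp, lambda, D, X0 = 0) {
  a <- exp(-lambda * dt_samp)
  s <- sqrt((D / lambda) * (1 - a^2))
  x <- numeric(n)
  x[1] <- X0
  eps <- stats::rnorm(n - 1)
  for (i in 2:n) x[i] <- a * x[i - 1] + s * eps[i - 1]
  x
}

#' Fit Ornstein-Uhlenbeck parameters to diffusion measurements
#'
#' Nonlinear least-squares fit of either the point-conditioned
#' `G(0, dt)` or an ensemble variance curve to
#' `(D/lambda)(1 - exp(-2 lambda dt))` (see [ou_G()] for why the
#' conditional estimator takes this form rather than the unconditional
#' stationary MSD).
#'
#' @param dt Lag or time grid (ms).
#' @param y Measured `G(0, dt)` or variance values.
#' @param lambda_init Initial decay rate (1/ms); e.g. from
#'   [fit_drift_rate()].
#' @param type `"G"` or `"variance"`.
#' @param weights Optional weights (e.g. `1/se^2`).
#' @param lambda_fixed If given, `lambda` is held at this value and only
#'   `D` is fitted. Useful when `lambda` is measured independently (from
#'   the conditional drift): in saturating-variance curves `lambda` and
#'   `D` are strongly degenerate.
#' @return An `"ou_fit"`: list with `lambda` (1/ms), `D` (X^2/ms), standard
#'   errors, the fit object, and the window used.
#' @export
fit_ou <- function(dt, y, lambda_init = 1 / max(dt), type = c("G", "variance"),
                   weights = NULL, lambda_fixed = NULL) {
  type <- match.arg(type)
  keep <- is.finite(y) & is.finite(dt)
  dt <- dt[keep]; y <- y[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(dt) < 5) stop("need at least 5 lag points for an OU fit")
  df <- data.frame(dt = dt, y = y)
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  if (is.null(lambda_fixed)) {
    form <- y ~ (D / lambda) * (1 - exp(-2 * lambda * dt))
    D_init <- max(y, na.rm = TRUE) * lambda_init
    if (D_init <= 0) D_init <- 1e-12
    start <- list(lambda = lambda_init, D = D_init)
  } else {
    df$lambda <- lambda_fixed
    form <- y ~ (D / lambda) * (1 - exp(-2 * lambda * dt))
    D_init <- max(y, na.rm = TRUE) * lambda_fixed
    if (D_init <= 0) D_init <- 1e-12
    start <- list(D = D_init)
  }
  fit <- minpack.lm::nlsLM(form, data = df, start = start, weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  lambda_hat <- if (is.null(lambda_fixed)) unname(cf["lambda"]) else lambda_fixed
  if (lambda_hat <= 0 || cf["D"] <= 0)
    stop("OU fit converged to non-positive parameters")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  structure(list(lambda = lambda_hat, D = unname(cf["D"]),
                 se = se, fit = fit, type = type,
                 window = range(dt)),
            class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("OU fit (%s): lambda = %.4g /ms (1/lambda = %.3g ms), D = %.4g /ms\n",
              x$type, x$lambda, 1 / x$lambda, x$D))
  cat(sprintf("  D = %.4g per 10 ms; window %.3g .. %.3g ms\n",
              x$D * 10, x$window[1], x$window[2]))
  invisible(x)
}

#' Across-replica variance as a function of time
#'
#' Variance over an ensemble of replica trajectories at each sample time,
#' with bootstrap standard errors (resampling replicas).
#'
#' @param Xmat Matrix, one column per replica, rows are sample times.
#' @param times Sample times (ms).
#' @param n_boot Bootstrap resamples.
#' @return Data frame with `time`, `var`, `se`.
#' @export
ensemble_variance <- function(Xmat, times = seq_len(nrow(Xmat)),
                              n_boot = 200L) {
  Xmat <- as.matrix(Xmat)
  R <- ncol(Xmat)
  if (R < 2) stop("need at least 2 replicas")
  v <- apply(Xmat, 1, stats::var)
  bs <- replicate(n_boot, {
    j <- sample.int(R, R, replace = TRUE)
    apply(Xmat[, j, drop = FALSE], 1, stats::var)
  })
  data.frame(time = times, var = v, se = apply(bs, 1, stats::sd))
}

#' Population-averaged single-neuron autocorrelation
#'
#' `q_i(dt) = (1/n) sum_k <sigma_k(t + dt) sigma_k(t)>` over the recorded
#' neurons of each population. The initial slope is estimated by a linear
#' fit of `q` over the first lags (up to `slope_window` ms).
#'
#' @param states Snapshot matrix from [run_network()] (attributes `times`
#'   and `pop`), or any 0/1 matrix with those attributes.
#' @param lags Lags (ms); rounded to multiples of the snapshot interval.
#' @param slope_window Fit window for the initial slope (ms).
#' @return An `"autocorrelation_q"`: list with `lags` (ms), `q` (matrix,
#'   lag x population), `q0`, `slope0` (per population, 1/ms).
#' @export
autocorrelation_q <- function(states, lags, slope_window = NULL) {
  times <- attr(states, "times")
  pop <- attr(states, "pop")
  dt_samp <- times[2] - times[1]
  if (is.null(slope_window)) slope_window <- max(lags) / 3
  lag_s <- unique(c(0L, as.integer(round(lags / dt_samp))))
  n <- nrow(states)
  S <- states
  storage.mode(S) <- "double"
  qs <- matrix(NA_real_, length(lag_s), 4)
  for (il in seq_along(lag_s)) {
    L <- lag_s[il]
    pr <- colMeans(S[1:(n - L), , drop = FALSE] * S[(1 + L):n, , drop = FALSE])
    qs[il, ] <- vapply(1:4, function(p) mean(pr[pop == p]), numeric(1))
  }
  lag_ms <- lag_s * dt_samp
  slope0 <- vapply(1:4, function(p) {
    w <- lag_ms <= slope_window
    if (sum(w) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(qs[w, p] ~ lag_ms[w]))[2])
  }, numeric(1))
  structure(list(lags = lag_ms, q = qs, q0 = qs[1, ], slope0 = slope0),
            class = "autocorrelation_q")
}

#' Short-lag diffusion predicted from single-neuron autocorrelations
#'
#' For lags much shorter than the update interval the mean squared
#' displacement of the projection grows linearly, with a rate set entirely
#' by the initial decay of the single-neuron autocorrelations:
#' `G(X, dt)/dt = (2/N) sum_j (v0_j)^2 (-dq_j/dt at 0)`. No fitting
#' parameters are involved.
#'
#' @param slopes Length-4 vector of initial autocorrelation slopes
#'   (1/ms; from [autocorrelation_q()]).
#' @param basis A [projection_basis()].
#' @param N Neurons per population.
#' @return Predicted `G/dt` (1/ms).
#' @export
short_time_G <- function(slopes, basis, N) {
  (2 / N) * sum(basis$v0^2 * (-slopes))
}

#' Pairwise-averaged cross-covariance of recorded neurons
#'
#' The unbiased single-pair lagged covariance
#' `C_ij(m) = 1/(M-|m|) sum_a s_i(a+m) s_j(a) - (1/M sum s_i)(1/M sum s_j)`
#' averaged over pairs: over all ordered pairs `i != j` divided by
#' `n(n-1)/2` for a single population (self-pairs excluded), or over all
#' `n_i n_j` pairs for two different populations.
#'
#' @param Si Matrix of binary series, one column per neuron (samples in
#'   rows, spacing `dt_samp`).
#' @param Sj Second population's matrix, or `NULL` for within-population.
#' @param lags Lags in ms (positive and/or negative).
#' @param dt_samp Sampling interval of the series (ms).
#' @return Data frame with `lag` (ms) and `C`.
#' @export
pair_cross_covariance <- function(Si, Sj = NULL, lags, dt_samp) {
  same <- is.null(Sj)
  if (same) Sj <- Si
  Si <- as.matrix(Si); Sj <- as.matrix(Sj)
  storage.mode(Si) <- "double"; storage.mode(Sj) <- "double"
  M <- nrow(Si)
  ni <- ncol(Si); nj <- ncol(Sj)
  if (same && ni < 2) stop("need at least 2 neurons")
  Pi <- rowSums(Si); Pj <- rowSums(Sj)
  mu_i <- colMeans(Si); mu_j <- colMeans(Sj)
  mean_term <- sum(mu_i) * sum(mu_j) - if (same) sum(mu_i * mu_j) else 0
  npairs <- if (same) 0.5 * ni * (ni - 1) else ni * nj
  lag_s <- as.integer(round(lags / dt_samp))
  C <- vapply(lag_s, function(L) {
    aL <- abs(L)
    if (aL >= M) return(NA_real_)
    # sum over ordered pairs of lagged products via population sums
    ia <- if (L >= 0) (1 + aL):M else 1:(M - aL)
    ib <- if (L >= 0) 1:(M - aL) else (1 + aL):M
    tot <- sum(Pi[ia] * Pj[ib])
    if (same) tot <- tot - sum(rowSums(Si[ia, , drop = FALSE] * Sj[ib, , drop = FALSE]))
    tot / (M - aL) - mean_term
  }, numeric(1)) / npairs
  data.frame(lag = lag_s * dt_samp, C = C)
}

#' Population-activity cross-covariance
#'
#' The lagged covariance of two population mean-activity series,
#' `C(m) = 1/(M-|m|) sum_a x(a+m) y(a) - (1/M sum x)(1/M sum y)`.
#' Relative to the pairwise average this estimator includes the
#' auto-covariance terms, whose contribution is of order `1/N`.
#'
#' @param x,y Numeric series on a uniform grid (e.g. columns of a
#'   population trace).
#' @param lags Lags in ms.
#' @param dt_samp Sampling interval (ms).
#' @return Data frame with `lag` (ms) and `C`.
#' @export
population_cross_covariance <- function(x, y, lags, dt_samp) {
  M <- length(x)
  stopifnot(length(y) == M)
  mean_term <- mean(x) * mean(y)
  lag_s <- as.integer(round(lags / dt_samp))
  C <- vapply(lag_s, function(L) {
    aL <- abs(L)
    if (aL >= M) return(NA_real_)
    ia <- if (L >= 0) (1 + aL):M else 1:(M - aL)
    ib <- if (L >= 0) 1:(M - aL) else (1 + aL):M
    sum(x[ia] * y[ib]) / (M - aL) - mean_term
  }, numeric(1))
  data.frame(lag = lag_s * dt_samp, C = C)
}
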