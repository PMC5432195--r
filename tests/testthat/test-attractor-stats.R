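test_that("projection is zero at the fixed point and linear along the line", {
  p <- network_params(N = 2000, K = 1000)
  b <- projection_basis(p, K = Inf)
  tr <- population_trace(1:3, rbind(b$m0, b$m0, b$m0))
  expect_equal(as.numeric(project(tr, b)), rep(0, 3))
  # mirrored symmetric trajectory: X identically zero while m fluctuates
  msym <- rbind(c(0.24, 0.1, 0.24, 0.1), c(0.3, 0.12, 0.3, 0.12))
  expect_equal(as.numeric(project(population_trace(1:2, msym), b)),
               c(0, 0), tolerance = 1e-12)
})

test_that("drift and diffusion moments recover a known OU generator", {
  set.seed(31)
  lam <- 0.01; D <- 1e-5 # 1/ms, X^2/ms
  # study conditions: many trials, each much longer than 1/lambda
  paths <- lapply(1:200, function(i) simulate_ou(1e4, 1, lam, D))
  dd <- drift_diffusion(paths, 1, X_grid = seq(-0.04, 0.04, by = 0.01),
                        lags = c(1, 2, 5, 10), delta = 2e-3)
  d1 <- dd[dd$dt == 1 & !is.na(dd$F), ]
  # F(X, dt)/dt close to -lambda X across the grid
  expect_true(all(abs(d1$F - d1$X * (exp(-lam) - 1)) < 2.5 * d1$se_F))
  # G(0, dt)/dt close to 2D at small lags
  g0 <- dd[abs(dd$X) < 1e-12, ]
  expect_true(all(abs(g0$G / g0$dt - 2 * D) < 0.1 * 2 * D))
  # constant trace: F = G = 0 in its own cell
  ddc <- drift_diffusion(rep(0.01, 2000), 1, X_grid = 0.01, lags = c(1, 5),
                         delta = 1e-3)
  expect_equal(ddc$F, c(0, 0))
  expect_equal(ddc$G, c(0, 0))
  # empty cells are flagged as NA, never zero
  dde <- drift_diffusion(paths[[1]], 1, X_grid = 5, lags = 1, delta = 1e-3)
  expect_true(is.na(dde$F) && is.na(dde$G))
  expect_equal(dde$count, 0)
})

test_that("OU fits recover generating parameters", {
  # zero-noise fit: data generated exactly from the OU formulas
  lam <- 0.004; D <- 2e-6
  dt <- c(5, 10, 20, 50, 100, 200, 400, 800, 1600)
  f1 <- fit_ou(dt, ou_G(dt, lam, D), lambda_init = 0.01)
  expect_equal(f1$lambda, lam, tolerance = 1e-8)
  expect_equal(f1$D, D, tolerance = 1e-8)
  f2 <- fit_ou(dt, ou_variance(dt, lam, D), lambda_init = 0.01,
               type = "variance")
  expect_equal(f2$lambda, lam, tolerance = 1e-8)
  # one-parameter fit with the decay rate held fixed
  f3 <- fit_ou(dt, ou_variance(dt, lam, D), type = "variance",
               lambda_fixed = lam)
  expect_equal(f3$D, D, tolerance = 1e-10)
  # simulated paths: recovery within 10%
  set.seed(41)
  paths <- lapply(1:200, function(i) simulate_ou(25000, 5, 0.01, 1e-5))
  dd <- drift_diffusion(paths, 5, X_grid = 0,
                        lags = c(5, 10, 25, 50, 100, 200, 400, 800),
                        delta = 2e-3)
  g0 <- dd[!is.na(dd$G), ]
  fit <- fit_ou(g0$dt, g0$G, lambda_init = 0.02)
  expect_equal(fit$lambda, 0.01, tolerance = 0.1)
  expect_equal(fit$D, 1e-5, tolerance = 0.1)
  expect_error(fit_ou(c(1, 2), c(1, 2), 0.1), "at least 5")
})

test_that("drift-rate estimate from F matches the generator", {
  set.seed(43)
  paths <- lapply(1:100, function(i) simulate_ou(1e4, 1, 0.01, 1e-5))
  dd <- drift_diffusion(paths, 1, X_grid = seq(-0.04, 0.04, by = 0.01),
                        lags = c(10, 20), delta = 2e-3)
  fr <- fit_drift_rate(dd, dt = 10)
  expect_equal(fr$lambda, 0.01, tolerance = 0.1)
})

test_that("ensemble variance matches the OU release curve and flags degenerate input", {
  set.seed(51)
  lam <- 0.005; D <- 1e-5
  R <- 400
  Xmat <- vapply(1:R, function(r) simulate_ou(2000, 1, lam, D, X0 = 0),
                 numeric(2000))
  ev <- ensemble_variance(Xmat, times = 1:2000, n_boot = 100)
  th <- ou_variance(ev$time, lam, D)
  sel <- ev$time %in% c(100, 500, 1000, 2000)
  expect_true(all(abs(ev$var[sel] - th[sel]) < 2.5 * ev$se[sel]))
  # identical replicas: variance identically zero
  ev0 <- ensemble_variance(matrix(rep(simulate_ou(100, 1, lam, D), 3), 100, 3),
                           n_boot = 10)
  expect_equal(ev0$var, rep(0, 100))
  expect_error(ensemble_variance(matrix(1, 5, 1)), "2 replicas")
})

test_that("autocorrelation matches the closed form for Bernoulli refresh dynamics", {
  # surrogate: each neuron refreshed at Poisson rate 1/tau to on with P = p
  set.seed(61)
  n <- 400; tau <- 10; pr <- 0.3
  dt <- 0.5; steps <- 8000
  S <- matrix(0L, steps, n)
  s <- as.integer(runif(n) < pr)
  for (t in seq_len(steps)) {
    upd <- runif(n) < dt / tau
    s[upd] <- as.integer(runif(sum(upd)) < pr)
    S[t, ] <- s
  }
  attr(S, "times") <- seq_len(steps) * dt
  attr(S, "pop") <- rep(1:4, each = n / 4)
  qc <- autocorrelation_q(S, lags = seq(0.5, 12, by = 0.5), slope_window = 3)
  expect_equal(qc$q0, rep(pr, 4), tolerance = 0.05)
  th <- pr^2 + pr * (1 - pr) * exp(-qc$lags / tau)
  expect_lt(max(abs(rowMeans(qc$q) - th)), 0.01 * pr)
  expect_equal(mean(qc$slope0), -pr * (1 - pr) / tau, tolerance = 0.1)
  # frozen dynamics: q constant at q(0)
  Sf <- matrix(rep(as.integer(runif(n) < pr), each = 100), 100, n)
  attr(Sf, "times") <- seq_len(100) * dt
  attr(Sf, "pop") <- rep(1:4, each = n / 4)
  qf <- autocorrelation_q(Sf, lags = seq(0.5, 10, by = 0.5))
  expect_true(all(abs(qf$q - matrix(qf$q[1, ], nrow(qf$q), 4, byrow = TRUE))
                  < 1e-12))
})

test_that("short-lag prediction scales as 1/N and vanishes for frozen states", {
  b <- list(v0 = c(0.7, -0.4, -0.7, 0.4))
  slopes <- c(-0.009, -0.005, -0.009, -0.005)
  g1 <- short_time_G(slopes, b, 1e4)
  expect_equal(short_time_G(slopes, b, 2e4), g1 / 2)
  expect_equal(short_time_G(rep(0, 4), b, 1e4), 0)
  expect_equal(g1, (2 / 1e4) * sum(b$v0^2 * (-slopes)))
})

test_that("pairwise covariance reproduces by-hand arithmetic on a toy pair", {
  s1 <- c(1, 0, 1, 1, 0, 0)
  s2 <- c(0, 1, 1, 0, 1, 0)
  M <- 6
  # single ordered pair (1,2) and (2,1) at lag +1 sample, by hand
  c12 <- sum(s1[2:6] * s2[1:5]) / 5 - mean(s1) * mean(s2)
  c21 <- sum(s2[2:6] * s1[1:5]) / 5 - mean(s1) * mean(s2)
  by_hand <- (c12 + c21) / 1 # sum over ordered pairs / (0.5 n (n-1)), n = 2
  pc <- pair_cross_covariance(cbind(s1, s2), NULL, lags = 1, dt_samp = 1)
  expect_equal(pc$C, by_hand)
  # identical constant sequences: zero covariance at all lags
  pc0 <- pair_cross_covariance(cbind(rep(1, 10), rep(1, 10)), NULL,
                               lags = c(-2, 0, 2), dt_samp = 1)
  expect_equal(pc0$C, rep(0, 3))
})

test_that("pairwise estimator noise falls with the number of neurons", {
  set.seed(71)
  M <- 600; dt <- 1
  noise_level <- function(n) {
    S <- matrix(as.integer(runif(M * n) < 0.2), M, n) # independent: true C = 0
    pc <- pair_cross_covariance(S, NULL, lags = seq(-20, 20, by = 2),
                                dt_samp = dt)
    mean(pc$C^2)
  }
  r <- mean(vapply(1:8, function(i) noise_level(10) / noise_level(40),
                   numeric(1)))
  # variance of the pair average scales roughly as 1/n^2 pairs ~ (40/10)^2
  expect_gt(r, 4)
})

test_that("population covariance is symmetric under lag reversal and index swap", {
  set.seed(81)
  x <- as.numeric(stats::filter(rnorm(3000), rep(0.2, 5), sides = 1))
  y <- as.numeric(stats::filter(rnorm(3000), rep(0.2, 5), sides = 1))
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  lags <- seq(-10, 10, by = 1)
  cxy <- population_cross_covariance(x, y, lags, 1)
  cyx <- population_cross_covariance(y, x, lags, 1)
  expect_equal(cxy$C, rev(cyx$C), tolerance = 1e-12)
  # at lag 0 the estimator is the plain covariance (population normalization)
  c0 <- population_cross_covariance(x, y, 0, 1)$C
  expect_equal(c0, mean(x * y) - mean(x) * mean(y), tolerance = 1e-12)
})

test_that("unconditional MSD of an OU path follows the stationary formula", {
  set.seed(91)
  lam <- 0.01; D <- 1e-5
  paths <- lapply(1:50, function(i) simulate_ou(2e4, 1, lam, D))
  msd <- msd_curve(paths, 1, lags = c(10, 50, 100, 300, 800))
  th <- (2 * D / lam) * (1 - exp(-lam * msd$dt))
  expect_lt(max(abs(msd$msd / th - 1)), 0.05)
})
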