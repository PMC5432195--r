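p_std <- network_params(N = 2000, K = 1000) # standard couplings, J_tilde = 1.5

test_that("gaussian tail and inverse are consistent and monotone", {
  expect_equal(gaussian_tail(0), 0.5)
  expect_equal(gaussian_tail(-Inf), 1)
  expect_equal(gaussian_tail(Inf), 0)
  expect_equal(gaussian_tail_inv(gaussian_tail(1.2345)), 1.2345,
               tolerance = 1e-10)
  x <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(gaussian_tail(x)) < 0))
  expect_error(gaussian_tail_inv(0), "\\(0, 1\\)")
  expect_error(gaussian_tail_inv(1), "\\(0, 1\\)")
})

test_that("input statistics match hand arithmetic at the symmetric line point", {
  m <- c(0.25, 0.1, 0.25, 0.1)
  st <- input_stats(m, p_std, K = 1000)
  # the balance bracket vanishes exactly on the line, so u = -T
  expect_equal(st$bracket[1], 0)
  expect_equal(st$u[1], -p_std$T[1])
  expect_equal(st$alpha[1], 0.25 + 16 * 0.1)
  expect_equal(st$alpha[2], 0.25 + 6.25 * 0.1)
  ps <- network_params(N = 2000, K = 1000, cross_mode = "sparse")
  sts <- input_stats(m, ps, K = 1000)
  expect_equal(sts$alpha[1], 1.85 + 1.5^2 * 0.1)
})

test_that("the infinite-K line satisfies the singular linear system exactly", {
  p <- p_std
  Jt <- p$J_E - p$J_I
  M <- rbind(c(1, -p$J_E, 0, -Jt), c(1, -p$J_I, 0, 0),
             c(0, -Jt, 1, -p$J_E), c(0, 0, 1, -p$J_I))
  b <- c(-p$E0, 0, -p$E0, 0)
  for (x in c(0.05, 0.25, 0.45)) {
    m <- line_kinf(x, p)
    expect_equal(as.vector(M %*% m), b, tolerance = 1e-14)
  }
  expect_equal(line_kinf(0.25, p), c(0.25, 0.1, 0.25, 0.1))
  expect_equal(line_x_range(p)[2], 0.5)
  expect_equal(line_kinf(1e-9, p), c(0, 0, 0.5, 0.2), tolerance = 1e-6)
  expect_error(line_kinf(0.6, p), "interval")
  # the null vector of M is the slow direction pattern
  r0 <- c(1, 1 / p$J_I, -1, -1 / p$J_I)
  expect_equal(as.vector(M %*% r0), rep(0, 4), tolerance = 1e-14)
})

test_that("mean-field dynamics vanish at the solved fixed point", {
  fp <- solve_fixed_point(p_std, K = 1000)
  expect_lt(fp$residual, 1e-12)
  expect_equal(mf_rhs(fp$m, p_std, K = 1000), rep(0, 4), tolerance = 1e-11)
  expect_true(all(fp$m > 0 & fp$m < 1))
  # symmetric by construction
  expect_equal(fp$m[1], fp$m[3])
  expect_equal(fp$m[2], fp$m[4])
})

test_that("empty network with positive drive has positive excitatory growth", {
  d <- mf_rhs(c(1e-12, 1e-12, 1e-12, 1e-12), p_std, K = 1000)
  expect_gt(d[1], 0)
})

test_that("fixed point agrees with an independent bisection on the symmetric subspace", {
  # oracle: 1-D bisection over m_E with m_I eliminated by its own equation
  p <- p_std
  K <- 1000
  res_E <- function(mE) {
    mI <- balancedline:::solve_inhibitory(mE, p, K)
    st <- input_stats(c(mE, mI, mE, mI), p, K)
    mE - gaussian_tail(-st$u[1] / sqrt(st$alpha[1]))
  }
  root <- stats::uniroot(res_E, c(0.01, 0.6), tol = 1e-14)$root
  fp <- solve_fixed_point(p, K = K)
  expect_equal(fp$m[1], root, tolerance = 1e-9)
})

test_that("solver is robust to a far-off guess or reports failure explicitly", {
  out <- tryCatch(solve_fixed_point(p_std, guess = rep(0.99, 4), K = 1000),
                  error = function(e) e)
  if (inherits(out, "error")) {
    expect_match(conditionMessage(out), "converge|saturat")
  } else {
    fp <- solve_fixed_point(p_std, K = 1000)
    expect_equal(out$m, fp$m, tolerance = 1e-8)
  }
})

test_that("analytic partials match central finite differences", {
  p <- p_std
  K <- 1000
  m <- c(0.22, 0.09, 0.27, 0.11)
  f <- balancedline:::mf_partials(m, p, K)
  h <- 1e-6
  for (j in 1:4) {
    mp <- m; mm <- m
    mp[j] <- m[j] + h; mm[j] <- m[j] - h
    Hp <- with(input_stats(mp, p, K), gaussian_tail(-u / sqrt(alpha)))
    Hm <- with(input_stats(mm, p, K), gaussian_tail(-u / sqrt(alpha)))
    expect_equal(f[, j], (Hp - Hm) / (2 * h), tolerance = 1e-6)
  }
  # sparse cross mode adds alpha dependence on the opposing activity
  ps <- network_params(N = 2000, K = 1000, cross_mode = "sparse")
  fs <- balancedline:::mf_partials(m, ps, K)
  for (j in c(2, 4)) {
    mp <- m; mm <- m
    mp[j] <- m[j] + h; mm[j] <- m[j] - h
    Hp <- with(input_stats(mp, ps, K), gaussian_tail(-u / sqrt(alpha)))
    Hm <- with(input_stats(mm, ps, K), gaussian_tail(-u / sqrt(alpha)))
    expect_equal(fs[, j], (Hp - Hm) / (2 * h), tolerance = 1e-6)
  }
})

test_that("closed-form symmetric eigenvalues match the numerical eigendecomposition", {
  fp <- solve_fixed_point(p_std, K = 1000)
  J <- jacobian(fp, p_std, K = 1000)
  ev_num <- sort(Re(J$eigenvalues))
  ev_cf <- sort(Re(J$closed_form))
  expect_lt(max(abs(ev_num - ev_cf)), 1e-10)
  # Jacobian rows follow the block sparsity pattern
  expect_equal(J$A[2, 3], 0)
  expect_equal(J$A[2, 4], 0)
  expect_equal(J$A[4, 1], 0)
  expect_equal(J$A[1, 3], 0)
})

test_that("the tuning identity forces a zero eigenvalue for random admissible partials", {
  set.seed(5)
  tau <- 0.8
  for (rep in 1:20) {
    f <- matrix(0, 4, 4)
    f[1, 1] <- runif(1, 0.5, 8); f[2, 2] <- -runif(1, 0.5, 8)
    f[1, 2] <- -runif(1, 1, 10); f[2, 1] <- runif(1, 1, 10)
    f[1, 4] <- tuned_f14(f)
    f[3, 3] <- f[1, 1]; f[4, 4] <- f[2, 2]; f[3, 4] <- f[1, 2]
    f[3, 2] <- f[1, 4]; f[4, 3] <- f[2, 1]
    ev <- symmetric_eigenvalues(f, tau)
    expect_lt(min(abs(Re(ev))), 1e-10)
    # and the nullcline slope equals -1 at that point
    expect_equal(nullcline_slope(f), -1, tolerance = 1e-10)
  }
})

test_that("tuned coupling: exact at infinite K, near 1.7 at K = 1000, decreasing in K", {
  p <- p_std
  expect_identical(tune_jtilde(p, K = Inf), p$J_E - p$J_I)
  jt1000 <- tune_jtilde(p, K = 1000)
  expect_equal(round(jt1000, 1), 1.7)
  jts <- vapply(c(100, 500, 1000, 5000), function(K) tune_jtilde(p, K),
                numeric(1))
  expect_true(all(diff(jts) < 0))
  expect_true(all(jts > p$J_E - p$J_I))
})

test_that("slow eigenvalue is linear in the coupling with slope growing as sqrt(K)", {
  p <- p_std
  slopes <- vapply(c(100, 400), function(K) {
    jt <- tune_jtilde(p, K)
    tab <- lambda_vs_jtilde(p, K, jt + c(-0.005, -0.0025, 0, 0.0025, 0.005) * jt)
    fit <- stats::lm(lambda ~ poly(J_tilde, 2, raw = TRUE), data = tab)
    cf <- stats::coef(fit)
    # quadratic contribution under 5% of the linear term over the window
    expect_lt(abs(cf[3] * (0.005 * jt)^2), 0.05 * abs(cf[2] * 0.005 * jt))
    stats::coef(stats::lm(lambda ~ J_tilde, data = tab))[2]
  }, numeric(1))
  expect_equal(unname(slopes[2] / slopes[1]), 2, tolerance = 0.1)
  # stability below tuning, zero at tuning
  jt <- tune_jtilde(p, 400)
  expect_lt(balancedline:::lambda_slow(p, 400, jt - 0.05), 0)
  expect_lt(abs(balancedline:::lambda_slow(p, 400, jt)), 1e-8)
})

test_that("projection basis matches the null structure and normalization", {
  p <- p_std
  b_inf <- projection_basis(p, K = Inf)
  expect_equal(b_inf$r0, c(1, 0.4, -1, -0.4))
  expect_equal(sum(b_inf$v0 * b_inf$r0), 1)
  # finite K at tuned coupling: v0.r0 = 1, r0 close to the pattern
  pt <- p
  pt$J_tilde <- tune_jtilde(p, 1000)
  b <- projection_basis(pt, K = 1000)
  expect_equal(sum(b$v0 * b$r0), 1, tolerance = 1e-10)
  expect_equal(b$r0, c(1, 0.4, -1, -0.4), tolerance = 0.05)
  expect_lt(abs(b$lambda), 1e-6)
  # along the line, X(m(x)) = x - x_sym
  b2 <- b_inf
  xs <- line_x_symmetric(p)
  for (x in c(0.1, 0.3, 0.4)) {
    m <- line_kinf(x, p)
    expect_equal(sum(b2$v0 * (m - b2$m0)), x - xs, tolerance = 1e-10)
  }
})

test_that("eigenvalue real parts are negative along the attractor except the slow one", {
  pt <- p_std
  pt$J_tilde <- tune_jtilde(p_std, 1000)
  guessI <- function(m1) balancedline:::solve_inhibitory(m1, pt, 1000)
  nc <- nullclines(pt, 1000, seq(0.15, 0.35, by = 0.05))
  for (i in seq_len(nrow(nc))) {
    m1 <- nc$m1[i]; m3 <- nc$m3_null1[i]
    m <- c(m1, guessI(m1), m3, guessI(m3))
    J <- jacobian(m, pt, K = 1000)
    ev <- sort(Re(J$eigenvalues))
    expect_true(all(ev[1:3] < 0))
    expect_lt(abs(ev[4]), 0.15) # slow mode stays near zero along the line
  }
})

test_that("nullclines intersect at the symmetric point with slope -1 when tuned", {
  pt <- p_std
  pt$J_tilde <- tune_jtilde(p_std, 1000)
  fp <- solve_fixed_point(pt, K = 1000)
  h <- 1e-4
  nc <- nullclines(pt, 1000, fp$m[1] + c(-h, 0, h))
  # both curves pass through the symmetric fixed point
  expect_equal(nc$m3_null1[2], fp$m[3], tolerance = 1e-8)
  expect_equal(nc$m3_null3[2], fp$m[3], tolerance = 1e-8)
  slope1 <- (nc$m3_null1[3] - nc$m3_null1[1]) / (2 * h)
  expect_equal(slope1, -1, tolerance = 1e-6)
  # closed-form slope agrees with the numerically differentiated nullcline
  f <- balancedline:::mf_partials(fp$m, pt, 1000)
  expect_equal(1 / nullcline_slope(f), slope1, tolerance = 1e-4)
})

test_that("noiseless mean-field integration stays on the fixed point and decays at rate lambda", {
  p <- p_std
  fp <- solve_fixed_point(p, K = 1000)
  tr <- integrate_mf(fp$m, p, duration = 200, noise_sigma = 0, dt = 0.05)
  expect_lt(max(abs(tr$m[nrow(tr$m), ] - fp$m)), 1e-10)
  # central finite difference of the trajectory matches mf_rhs
  tr2 <- integrate_mf(fp$m + 0.01 * c(1, 0.4, -1, -0.4), p, duration = 20,
                      noise_sigma = 0, dt = 0.01)
  i <- 1000
  fd <- (tr2$m[i + 1, ] - tr2$m[i - 1, ]) / (2 * 0.01)
  # Euler trajectory: central difference matches the field to O(dt |f'|)
  expect_equal(fd, mf_rhs(tr2$m[i, ], p, K = 1000), tolerance = 0.02)
  # untuned J_tilde = 1.5: displacement along the line decays at rate |lambda|
  lam <- balancedline:::lambda_slow(p, 1000, 1.5) / p$tau_E # 1/ms
  b <- projection_basis(network_params(N = 2000, K = 1000,
                                       J_tilde = tune_jtilde(p, 1000)),
                        K = 1000)
  x0 <- 0.02
  tr3 <- integrate_mf(fp$m + x0 * b$r0, p, duration = 25, noise_sigma = 0,
                      dt = 0.01, dt_rec = 1)
  X <- as.vector(sweep(tr3$m, 2, fp$m) %*% b$v0)
  rate <- -stats::coef(stats::lm(log(X) ~ tr3$times))[2]
  expect_equal(unname(rate), -lam, tolerance = 0.1 * abs(lam))
})

test_that("noisy mean-field trajectories spread along the line only when tuned", {
  p <- p_std
  pt <- p
  pt$J_tilde <- tune_jtilde(p, 1000)
  sigma <- 1e-2 * sqrt(10)
  m0 <- solve_fixed_point(pt, K = 1000)$m
  b <- projection_basis(pt, K = 1000)
  set.seed(11)
  tr_t <- integrate_mf(m0, pt, duration = 3000, noise_sigma = sigma,
                       dt = 0.05, dt_rec = 1)
  pr <- project(tr_t, b, perpendicular = TRUE)
  # elongated cloud: spread along X much larger than perpendicular spread
  expect_gt(stats::sd(pr$X), 3 * stats::sd(pr$P1))
  set.seed(11)
  tr_u <- integrate_mf(m0, p, duration = 3000, noise_sigma = sigma,
                       dt = 0.05, dt_rec = 1)
  Xu <- project(tr_u, b)
  expect_gt(stats::sd(pr$X), 3 * stats::sd(Xu))
})
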