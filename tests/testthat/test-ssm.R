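test_that("discretize matches closed forms and the semigroup property", {
  # pure Brownian motion: F = I, Sigma = q dt I
  bm <- lti_system(matrix(0, 2, 2), diag(2) * 3, require_stable = FALSE)
  d <- discretize(bm, 0.4)
  expect_equal(d$F, diag(2), tolerance = 1e-12)
  expect_equal(d$Sigma, diag(2) * 3 * 0.4, tolerance = 1e-12)
  # scalar OU closed form
  ou <- lti_system(matrix(-1), matrix(2))
  d <- discretize(ou, log(2))
  expect_equal(d$F[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(d$Sigma[1, 1], 0.75, tolerance = 1e-12)
  # semigroup over random stable systems
  for (seed in 1:5) {
    sys <- rnd_stable_sys(3, seed)
    d1 <- discretize(sys, 0.3); d2 <- discretize(sys, 0.7)
    d12 <- discretize(sys, 1.0)
    expect_equal(d12$F, d2$F %*% d1$F, tolerance = 1e-10)
    expect_equal(d12$Sigma, d2$F %*% d1$Sigma %*% t(d2$F) + d2$Sigma,
                 tolerance = 1e-10)
  }
})

test_that("discretize is first-order correct as dt -> 0", {
  sys <- rnd_stable_sys(3, 11)
  dt <- 1e-6
  d <- discretize(sys, dt)
  # second-order remainders are O(dt^2) = 1e-12
  expect_lt(max(abs(d$F - (diag(3) + sys$W * dt))), 1e-10)
  expect_lt(max(abs(d$Sigma - sys$Q * dt)), 1e-10)
})

test_that("stationary covariance solves the Lyapunov equation", {
  sys <- rnd_stable_sys(4, 21)
  S <- stationary_cov(sys)
  expect_equal(sys$W %*% S + S %*% t(sys$W) + sys$Q, matrix(0, 4, 4),
               tolerance = 1e-10)
  # and equals the discrete fixed point for any step
  d <- discretize(sys, 0.8)
  expect_equal(S, d$F %*% S %*% t(d$F) + d$Sigma, tolerance = 1e-10)
})

test_that("kalman_filter log-likelihood matches trivial cases", {
  ou <- lti_system(matrix(-1), matrix(2))
  # T = 1, prior N(0,1), H = 1, R = 0, y = 0 -> standard normal at 0
  r <- kalman_filter(ou, 0, matrix(0), H = 1, R = 0, x0_mean = 0,
                     x0_cov = matrix(1))
  expect_equal(r$loglik, -0.5 * log(2 * pi), tolerance = 1e-12)
  # all steps missing -> loglik 0
  r <- kalman_filter(ou, 0:4, matrix(NA_real_, 5, 1), H = 1, R = 0.1)
  expect_equal(r$loglik, 0)
})

test_that("kalman_filter equals the dense joint-Gaussian oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    d <- c(2, 3, 5, 2)[seed]
    sys <- rnd_stable_sys(d, 100 + seed)
    T <- 6
    times <- cumsum(runif(T, 0.2, 1))
    H <- matrix(rnorm(2 * d), 2, d)
    m <- matrix(rnorm(T * 2), T, 2)
    R <- diag(c(0.3, 0.5))
    sim <- simulate_path(sys, times, H, m, R)
    y <- sim$y
    y[2, 1] <- NA; y[4, ] <- NA  # partial and full missingness
    kf <- kalman_filter(sys, times, y, H, m, R)
    expect_equal(kf$loglik, joint_loglik(sys, times, y, H, m, R),
                 tolerance = 1e-8)
    # total = sum of one-step predictive log densities
    expect_equal(kf$loglik, sum(kf$step_loglik), tolerance = 1e-12)
  }
})

test_that("likelihood is invariant to inserting unobserved steps", {
  sys <- rnd_stable_sys(2, 33)
  times <- seq(0, 5, by = 1)
  set.seed(33)
  sim <- simulate_path(sys, times, H = diag(2), R = diag(0.2, 2))
  l1 <- kalman_filter(sys, times, sim$y, H = diag(2), R = diag(0.2, 2))$loglik
  # split every interval by an extra fully-missing time point
  times2 <- sort(c(times, times[-1] - 0.5))
  y2 <- matrix(NA_real_, length(times2), 2)
  y2[match(times, times2), ] <- sim$y
  l2 <- kalman_filter(sys, times2, y2, H = diag(2), R = diag(0.2, 2))$loglik
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("an observation never inflates the filtered covariance", {
  sys <- rnd_stable_sys(3, 44)
  times <- seq(0, 4, by = 0.5)
  set.seed(44)
  sim <- simulate_path(sys, times, H = diag(3), R = diag(0.5, 3))
  kf <- kalman_filter(sys, times, sim$y, H = diag(3), R = diag(0.5, 3),
                      keep = TRUE)
  for (k in seq_along(times)) {
    dP <- kf$pred_cov[, , k] - kf$filt_cov[, , k]
    expect_gte(min(eigen(dP, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("kalman_smooth matches the joint-Gaussian conditional mean", {
  sys <- rnd_stable_sys(2, 55)
  T <- 5
  times <- seq(0, 2, length.out = T)
  set.seed(55)
  sim <- simulate_path(sys, times, H = matrix(c(1, 0), 1, 2), R = 0.3)
  ks <- kalman_smooth(sys, times, sim$y, H = matrix(c(1, 0), 1, 2), R = 0.3)
  # oracle: condition the dense joint state Gaussian on the observations
  S0 <- stationary_cov(sys)
  Fs <- lapply(seq_len(T - 1), function(k)
    discretize(sys, times[k + 1] - times[k])$F)
  Ss <- lapply(seq_len(T - 1), function(k)
    discretize(sys, times[k + 1] - times[k])$Sigma)
  P <- list(S0)
  for (k in 2:T) P[[k]] <- Fs[[k - 1]] %*% P[[k - 1]] %*% t(Fs[[k - 1]]) +
      Ss[[k - 1]]
  CC <- matrix(list(), T, T)
  for (j in 1:T) {
    CC[[j, j]] <- P[[j]]
    Phi <- diag(2)
    if (j < T) for (k in (j + 1):T) {
      Phi <- Fs[[k - 1]] %*% Phi
      CC[[j, k]] <- P[[j]] %*% t(Phi)
      CC[[k, j]] <- t(CC[[j, k]])
    }
  }
  Sx <- matrix(0, 2 * T, 2 * T)
  for (j in 1:T) for (k in 1:T)
    Sx[(j - 1) * 2 + 1:2, (k - 1) * 2 + 1:2] <- CC[[j, k]]
  Hbig <- matrix(0, T, 2 * T)
  for (k in 1:T) Hbig[k, (k - 1) * 2 + 1] <- 1
  Sy <- Hbig %*% Sx %*% t(Hbig) + diag(0.3, T)
  cond <- Sx %*% t(Hbig) %*% solve(Sy, drop(sim$y))
  expect_equal(as.vector(t(ks$smooth_mean)), as.vector(cond),
               tolerance = 1e-8)
  # final smoothed state equals the filtered one
  expect_equal(ks$smooth_mean[T, ], ks$filt_mean[T, ], tolerance = 1e-12)
})

test_that("simulate_path is exact, stationary and reproducible", {
  # Q = 0, R = 0: path equals the matrix-exponential solution
  sys <- lti_system(matrix(c(-1, 1, 0, -2), 2, 2), diag(0, 2))
  times <- seq(0, 3, by = 0.5)
  set.seed(1)
  sim <- simulate_path(sys, times, H = diag(2), R = diag(0, 2),
                       x0 = c(1, 2))
  for (k in seq_along(times)) {
    expect_equal(sim$states[k, ],
                 drop(discretize(sys, times[k])$F %*% c(1, 2)),
                 tolerance = 1e-10)
  }
  # scalar OU at stationarity: sample variance near q/(2a) = 1
  ou <- lti_system(matrix(-1), matrix(2))
  set.seed(7)
  n <- 1e5
  sim <- simulate_path(ou, seq(0, by = 0.1, length.out = n), H = 1, R = 0)
  v <- var(sim$states[, 1])
  rho <- exp(-0.1)
  se <- sqrt(2 / (n * (1 - rho) / (1 + rho)))
  expect_lt(abs(v - 1), 3 * se)
  # same seed -> identical draws
  set.seed(42); a <- simulate_path(ou, 0:9, H = 1, R = 0.1)
  set.seed(42); b <- simulate_path(ou, 0:9, H = 1, R = 0.1)
  expect_identical(a, b)
})

test_that("unstable drift is rejected where stability is required", {
  expect_error(lti_system(matrix(1), matrix(1)), "not stable")
  expect_error(lti_system(matrix(-1), matrix(-1)), "positive semidefinite")
})
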