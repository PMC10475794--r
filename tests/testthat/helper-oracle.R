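# Independent oracles and fixture builders shared across tests.

# random stable LTI system: eigenvalue real parts pushed below -0.3
rnd_stable_sys <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d, d)
  A <- A - diag(max(Re(eigen(A, only.values = TRUE)$values)) + 0.5, d)
  B <- matrix(rnorm(d * d), d, d)
  lti_system(A, crossprod(B) / d)
}

# dense joint-Gaussian log-density of the observations: stacks the state
# prior moments exactly (no filtering) and evaluates the multivariate
# normal at the observed entries
joint_loglik <- function(sys, times, y, H, m = NULL, R, x0_mean = NULL,
                         x0_cov = NULL) {
  y <- as.matrix(y)
  T <- nrow(y)
  d <- sys$d
  H <- matrix(H, ncol = d)
  c <- nrow(H)
  if (is.null(m)) m <- matrix(0, T, c)
  if (length(R) == c && is.null(dim(R))) R <- diag(R, c)
  R <- matrix(R, c, c)
  if (is.null(x0_mean)) x0_mean <- rep(0, d)
  if (is.null(x0_cov)) x0_cov <- stationary_cov(sys)

  Fs <- vector("list", T - 1)
  Ss <- vector("list", T - 1)
  if (T > 1) for (k in 2:T) {
    tr <- discretize(sys, times[k] - times[k - 1])
    Fs[[k - 1]] <- tr$F
    Ss[[k - 1]] <- tr$Sigma
  }
  mu <- matrix(0, T, d)
  mu[1, ] <- x0_mean
  P <- vector("list", T)
  P[[1]] <- x0_cov
  if (T > 1) for (k in 2:T) {
    mu[k, ] <- drop(Fs[[k - 1]] %*% mu[k - 1, ])
    P[[k]] <- Fs[[k - 1]] %*% P[[k - 1]] %*% t(Fs[[k - 1]]) + Ss[[k - 1]]
  }
  # cross-covariances C[j, k] = P_j Phi(j -> k)'
  C <- matrix(list(), T, T)
  for (j in 1:T) {
    C[[j, j]] <- P[[j]]
    Phi <- diag(d)
    if (j < T) for (k in (j + 1):T) {
      Phi <- Fs[[k - 1]] %*% Phi
      C[[j, k]] <- P[[j]] %*% t(Phi)
      C[[k, j]] <- t(C[[j, k]])
    }
  }
  obs_idx <- which(t(!is.na(y)))  # column-major over (channel, time)
  if (!length(obs_idx)) return(0)
  # stack observed scalars: for each time, observed channels
  rows <- list(); mean_v <- c(); val_v <- c()
  sel <- list()
  for (k in 1:T) {
    idx <- which(!is.na(y[k, ]))
    sel[[k]] <- idx
    if (length(idx)) {
      mean_v <- c(mean_v, drop(H[idx, , drop = FALSE] %*% mu[k, ]) +
                    m[k, idx])
      val_v <- c(val_v, y[k, idx])
    }
  }
  n <- length(val_v)
  Sig <- matrix(0, n, n)
  off <- cumsum(c(0, vapply(sel, length, 0L)))
  for (j in 1:T) for (k in 1:T) {
    ij <- sel[[j]]; ik <- sel[[k]]
    if (!length(ij) || !length(ik)) next
    blk <- H[ij, , drop = FALSE] %*% C[[j, k]] %*% t(H[ik, , drop = FALSE])
    if (j == k) blk <- blk + R[ij, ik, drop = FALSE]
    Sig[off[j] + seq_along(ij), off[k] + seq_along(ik)] <- blk
  }
  Sig <- (Sig + t(Sig)) / 2
  L <- chol(Sig)
  z <- backsolve(L, val_v - mean_v, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z * z)
}

# glucose record on a regular grid from explicit values
make_glucose_record <- function(times, values, meals = meal_log(),
                                missing = rep(FALSE, length(times))) {
  win <- c(floor(min(times, meals$times)), ceiling(max(times, meals$times)))
  participant_record(
    "TEST", list(glucose = sensor_series("glucose", times,
                                         ifelse(missing, NA_real_, values),
                                         missing = missing)),
    meals, window = win)
}

# cardio record with all three channels on one grid
make_cardio_record <- function(times, y, missing = NULL) {
  mk <- function(ch, v) {
    mi <- if (is.null(missing)) is.na(v) else missing
    sensor_series(ch, times, ifelse(mi, NA_real_, v), missing = mi)
  }
  participant_record("TEST",
                     list(activity = mk("activity", y[, 1]),
                          hr = mk("hr", y[, 2]),
                          hrv = mk("hrv", y[, 3])),
                     meal_log())
}

# reduced HMC settings for tests (documented scale-down of the reference
# 4 x 10,000 protocol)
test_hmc_config <- function(n_draws = 1000) {
  hmc_config(n_chains = 1, n_draws = n_draws, n_burnin = 500,
             stage1_draws = 300, stage1_burnin = 300)
}
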