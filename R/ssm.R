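#' Continuous-time linear time-invariant stochastic system
#'
#' The dynamic model `dx = W x dt + dB`, with drift matrix `W` and Brownian
#' diffusion covariance `Q`. All fitted models require `W` stable (all
#' eigenvalue real parts negative) so that a stationary distribution exists.
#'
#' @param W d x d drift matrix.
#' @param Q d x d symmetric positive semidefinite diffusion covariance.
#' @param require_stable error if `W` is not stable (default TRUE).
#' @return object of class `lti_system`.
#' @export
lti_system <- function(W, Q, require_stable = TRUE) {
  W <- as.matrix(W); Q <- as.matrix(Q)
  d <- nrow(W)
  stopifnot(ncol(W) == d, nrow(Q) == d, ncol(Q) == d)
  if (max(abs(Q - t(Q))) > 1e-10 * max(1, max(abs(Q))))
    stop("Q must be symmetric")
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev))))
    stop("Q must be positive semidefinite")
  if (require_stable && max(Re(eigen(W, only.values = TRUE)$values)) >= 0)
    stop("drift matrix W is not stable (eigenvalue with nonnegative real part)")
  structure(list(W = W, Q = Q, d = d), class = "lti_system")
}

#' @export
print.lti_system <- function(x, ...) {
  cat(sprintf("<lti_system: d = %d, max Re(eig W) = %.4g>\n", x$d,
              max(Re(eigen(x$W, only.values = TRUE)$values))))
  invisible(x)
}

#' Exact discretization of an LTI SDE over a time step
#'
#' Computes the state-transition matrix `F = expm(W dt)` and the exact
#' process-noise covariance `Sigma = int_0^dt expm(W s) Q expm(W' s) ds`
#' via the Van Loan matrix-fraction decomposition (no Euler approximation).
#'
#' @param sys an [lti_system()].
#' @param dt step length in hours (>= 0).
#' @return list with `F`, `Sigma`, `dt`.
#' @export
discretize <- function(sys, dt) {
  stopifnot(inherits(sys, "lti_system"), dt >= 0)
  if (dt == 0)
    return(list(F = diag(sys$d), Sigma = matrix(0, sys$d, sys$d), dt = 0))
  out <- cpp_discretize(sys$W, sys$Q, dt)
  list(F = out$F, Sigma = out$Sigma, dt = dt)
}

#' Stationary covariance of a stable LTI SDE
#'
#' Solves the continuous Lyapunov equation `W S + S W' + Q = 0`.
#'
#' @param sys an [lti_system()].
#' @return d x d covariance matrix.
#' @export
stationary_cov <- function(sys) {
  stopifnot(inherits(sys, "lti_system"))
  cpp_stationary_cov(sys$W, sys$Q)
}

# Build transition cubes for a time grid. Returns list(F, Sigma) as
# d x d x (T-1) arrays, caching unique dts.
transition_cubes <- function(sys, times) {
  T <- length(times)
  d <- sys$d
  if (T < 2) return(list(F = array(diag(d), c(d, d, 1)),
                         Sigma = array(0, c(d, d, 1))))
  dts <- diff(times)
  if (any(dts <= 0)) stop("times must be strictly increasing")
  key <- as.character(round(dts * 3.6e6))
  uk <- unique(key)
  Fc <- array(0, c(d, d, T - 1)); Sc <- array(0, c(d, d, T - 1))
  for (k in uk) {
    i <- which(key == k)
    tr <- discretize(sys, dts[i[1]])
    Fc[, , i] <- tr$F
    Sc[, , i] <- tr$Sigma
  }
  list(F = Fc, Sigma = Sc)
}

#' Kalman filter log-likelihood for irregularly sampled data
#'
#' Exact Gaussian log-likelihood of observations `y` under an
#' [lti_system()] with observation model `y_k = H x(t_k) + N(m_k, R)`.
#' Missing entries (`NA` in `y`) are handled by row deletion; fully missing
#' steps contribute prediction only and zero likelihood. The initial state
#' is the stationary distribution (mean zero) unless supplied.
#'
#' @param sys an [lti_system()].
#' @param times strictly increasing observation times (hours).
#' @param y T x c matrix of observations (`NA` = missing); a vector is
#'   treated as a single channel.
#' @param H c x d observation matrix.
#' @param m T x c deterministic observation mean offsets (default 0).
#' @param R c x c observation-noise covariance (a vector is taken as the
#'   diagonal).
#' @param x0_mean,x0_cov initial state distribution at `times[1]`; defaults
#'   to mean 0 and [stationary_cov()].
#' @param keep keep per-step filtered/predicted moments?
#' @param smooth also run the fixed-interval (RTS) smoother?
#' @return list with `loglik`, `step_loglik`, and (if requested) predicted,
#'   filtered and smoothed means/covariances.
#' @export
kalman_filter <- function(sys, times, y, H, m = NULL, R,
                          x0_mean = NULL, x0_cov = NULL,
                          keep = FALSE, smooth = FALSE) {
  stopifnot(inherits(sys, "lti_system"))
  y <- as.matrix(y)
  T <- nrow(y)
  stopifnot(length(times) == T)
  H <- matrix(H, ncol = sys$d)
  c <- nrow(H)
  stopifnot(ncol(y) == c)
  if (is.null(m)) m <- matrix(0, T, c)
  m <- as.matrix(m)
  if (length(R) == c && is.null(dim(R))) R <- diag(R, c)
  R <- matrix(R, c, c)
  if (is.null(x0_mean)) x0_mean <- rep(0, sys$d)
  if (is.null(x0_cov)) x0_cov <- stationary_cov(sys)
  tc <- transition_cubes(sys, times)
  cpp_kf(tc$F, tc$Sigma, H, m, R, y, x0_mean, x0_cov,
         keep = keep, smooth = smooth)
}

#' Fixed-interval smoother
#'
#' Convenience wrapper around [kalman_filter()] with `smooth = TRUE`.
#'
#' @inheritParams kalman_filter
#' @return as [kalman_filter()], including `smooth_mean` and `smooth_cov`.
#' @export
kalman_smooth <- function(sys, times, y, H, m = NULL, R,
                          x0_mean = NULL, x0_cov = NULL) {
  kalman_filter(sys, times, y, H, m, R, x0_mean, x0_cov,
                keep = TRUE, smooth = TRUE)
}

#' Simulate a latent path and noisy observations
#'
#' States follow the exact discrete-time recursion
#' `x_{k} = F x_{k-1} + N(0, Sigma)`; observations follow
#' `y_k = H x_k + N(m_k, R)`. Reproducible under `set.seed()`.
#'
#' @inheritParams kalman_filter
#' @param x0 initial state; default is a draw from the stationary
#'   distribution (or the zero vector if `Q = 0`).
#' @return list with `states` (T x d) and `y` (T x c).
#' @export
simulate_path <- function(sys, times, H, m = NULL, R, x0 = NULL) {
  d <- sys$d
  T <- length(times)
  H <- matrix(H, ncol = d)
  c <- nrow(H)
  if (is.null(m)) m <- matrix(0, T, c)
  m <- as.matrix(m)
  if (length(R) == c && is.null(dim(R))) R <- diag(R, c)
  R <- matrix(R, c, c)
  if (is.null(x0)) {
    S0 <- stationary_cov(sys)
    x0 <- drop(safe_chol(S0) %*% rnorm(d))
  }
  tc <- transition_cubes(sys, times)
  X <- matrix(0, T, d)
  X[1, ] <- x0
  if (T > 1) {
    for (k in 2:T) {
      S <- tc$Sigma[, , k - 1]
      X[k, ] <- drop(tc$F[, , k - 1] %*% X[k - 1, ]) +
        drop(safe_chol(S) %*% rnorm(d))
    }
  }
  E <- matrix(rnorm(T * c), T, c) %*% t(safe_chol(R))
  list(states = X, y = X %*% t(H) + m + E)
}

# lower-triangular factor tolerant of PSD (rank-deficient) matrices
safe_chol <- function(S) {
  S <- as.matrix(S)
  d <- nrow(S)
  if (all(S == 0)) return(matrix(0, d, d))
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), d)
}
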