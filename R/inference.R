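#' HMC sampler configuration
#'
#' Reference settings follow the two-stage protocol used for all model fits:
#' a first single-chain run with global step-size adaptation toward a 0.75
#' acceptance rate, whose posterior SDs set per-parameter step scales; then
#' 4 chains of 10,000 retained draws after 10,000 burn-in, with adaptation
#' restricted to the first 80% of burn-in, 5 leapfrog steps throughout. All
#' counts are configurable (tests and examples run heavily reduced).
#'
#' @param n_chains number of stage-2 chains.
#' @param n_draws retained draws per stage-2 chain.
#' @param n_burnin stage-2 burn-in per chain.
#' @param stage1_draws,stage1_burnin stage-1 counts.
#' @param leapfrog leapfrog steps per proposal.
#' @param target_accept target acceptance probability.
#' @param adapt_frac fraction of stage-2 burn-in during which the global
#'   step size adapts.
#' @param init_step initial global step size.
#' @return list of class `hmc_config`.
#' @export
hmc_config <- function(n_chains = 4, n_draws = 10000, n_burnin = 10000,
                       stage1_draws = 10000, stage1_burnin = 10000,
                       leapfrog = 5, target_accept = 0.75, adapt_frac = 0.8,
                       init_step = 0.1) {
  structure(list(n_chains = n_chains, n_draws = n_draws, n_burnin = n_burnin,
                 stage1_draws = stage1_draws, stage1_burnin = stage1_burnin,
                 leapfrog = leapfrog, target_accept = target_accept,
                 adapt_frac = adapt_frac, init_step = init_step),
            class = "hmc_config")
}

# one HMC chain with diagonal step scaling; logpost/grad take the
# unconstrained parameter vector. Returns draws, acceptance rate, step size.
hmc_chain <- function(logpost, grad, init, n_burnin, n_draws, leapfrog,
                      step, scales, target_accept, adapt_frac) {
  n_par <- length(init)
  q <- init
  lp <- logpost(q)
  if (!is.finite(lp)) stop("non-finite log posterior at the initial point")
  draws <- matrix(NA_real_, n_draws, n_par)
  n_total <- n_burnin + n_draws
  n_adapt <- floor(adapt_frac * n_burnin)
  acc <- 0
  log_eps <- log(step)
  for (it in seq_len(n_total)) {
    eps <- exp(log_eps) * scales
    p0 <- rnorm(n_par)
    p <- p0
    qn <- q
    gr <- grad(qn)
    p <- p + 0.5 * eps * gr
    for (l in seq_len(leapfrog)) {
      qn <- qn + eps * p
      gr <- grad(qn)
      if (any(!is.finite(gr))) { p[] <- NA; break }
      p <- p + (if (l < leapfrog) eps else 0.5 * eps) * gr
    }
    lpn <- if (anyNA(p)) -Inf else logpost(qn)
    log_alpha <- lpn - lp - 0.5 * sum(p^2) + 0.5 * sum(p0^2)
    alpha <- if (is.finite(log_alpha)) min(1, exp(log_alpha)) else 0
    if (runif(1) < alpha) { q <- qn; lp <- lpn }
    if (it <= n_adapt)
      log_eps <- log_eps + 0.25 / sqrt(it) * (alpha - target_accept)
    if (it > n_burnin) {
      draws[it - n_burnin, ] <- q
      acc <- acc + alpha
    }
  }
  list(draws = draws, accept_rate = acc / n_draws, step = exp(log_eps))
}

#' Maximum a posteriori estimate
#'
#' BFGS maximization of the unconstrained-scale log posterior, used to
#' initialise the sampler.
#'
#' @param logpost,grad log-posterior and gradient functions of the
#'   unconstrained parameter vector (`grad = NULL` uses finite differences
#'   inside `optim`).
#' @param init finite initial point.
#' @param maxit iteration cap.
#' @return list with `par`, `value` (log posterior at the optimum) and
#'   `convergence` (0 = converged; non-convergence raises a warning and
#'   returns the best point).
#' @export
map_estimate <- function(logpost, init, grad = NULL, maxit = 500) {
  fn <- function(u) {
    v <- logpost(u)
    if (!is.finite(v)) 1e10 else -v
  }
  gr <- if (is.null(grad)) NULL else function(u) -grad(u)
  opt <- optim(init, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("MAP optimization did not converge (code ", opt$convergence,
            "); returning best point")
  list(par = opt$par, value = -opt$value, convergence = opt$convergence)
}

#' Two-stage Hamiltonian Monte Carlo sampling
#'
#' Stage 1 runs a single adaptive chain from `init` (usually the MAP) with
#' unit step scales; the per-parameter posterior SDs of its draws become
#' the step scales of stage 2, which runs `n_chains` chains with global
#' step-size adaptation during the first `adapt_frac` of burn-in only.
#'
#' @inheritParams map_estimate
#' @param config an [hmc_config()].
#' @param par_names optional parameter names for the draw matrix.
#' @return object of class `posterior_samples`: `draws` (retained draws,
#'   rows = iterations stacked by chain), `chain` id per row, per-chain
#'   acceptance rates and step sizes.
#' @export
hmc_sample <- function(logpost, grad, init, config = hmc_config(),
                       par_names = NULL) {
  s1 <- hmc_chain(logpost, grad, init,
                  n_burnin = config$stage1_burnin,
                  n_draws = config$stage1_draws,
                  leapfrog = config$leapfrog, step = config$init_step,
                  scales = rep(1, length(init)),
                  target_accept = config$target_accept, adapt_frac = 1)
  scales <- apply(s1$draws, 2, sd)
  scales[!is.finite(scales) | scales < 1e-8] <- 1e-8
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chains[[ch]] <- hmc_chain(logpost, grad, s1$draws[nrow(s1$draws), ],
                              n_burnin = config$n_burnin,
                              n_draws = config$n_draws,
                              leapfrog = config$leapfrog, step = s1$step,
                              scales = scales,
                              target_accept = config$target_accept,
                              adapt_frac = config$adapt_frac)
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  if (!is.null(par_names)) colnames(draws) <- par_names
  structure(list(draws = draws,
                 chain = rep(seq_len(config$n_chains),
                             each = config$n_draws),
                 accept_rate = vapply(chains, `[[`, 0, "accept_rate"),
                 step = vapply(chains, `[[`, 0, "step"),
                 stage1_scales = scales),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples: %d draws x %d parameters, %d chain(s), mean acceptance %.2f>\n",
              nrow(x$draws), ncol(x$draws), length(unique(x$chain)),
              mean(x$accept_rate)))
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = k ln(n) - 2 loglik`, with `n` the number of non-missing scalar
#' observations.
#'
#' @param loglik log-likelihood at the parameter estimate.
#' @param k number of free parameters.
#' @param n number of observations (>= 1).
#' @return scalar BIC (lower is better).
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * loglik
}

#' Compare two models by BIC
#'
#' Uses a decisiveness cutoff of `2 ln(10) ~ 4.605`; a difference at the
#' boundary counts as decisive (documented convention).
#'
#' @param bic_full,bic_reduced BIC values on the same data.
#' @param cutoff decisiveness threshold.
#' @return `"full"`, `"reduced"` or `"inconclusive"`.
#' @export
compare_bic <- function(bic_full, bic_reduced, cutoff = 2 * log(10)) {
  d <- bic_reduced - bic_full
  if (abs(d) >= cutoff) {
    if (d > 0) "full" else "reduced"
  } else "inconclusive"
}

#' Explained variance of model predictions
#'
#' `1 - Var(y - ytilde) / Var(y)` per posterior draw; may be negative when
#' predictions are worse than the mean.
#'
#' @param y observed values (missing entries `NA` are dropped pairwise).
#' @param ytilde predictions: a vector, or a matrix with one column per
#'   posterior draw.
#' @return scalar, or vector with one entry per draw.
#' @export
explained_variance <- function(y, ytilde) {
  ytilde <- as.matrix(ytilde)
  ok <- is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 paired observations")
  y <- y[ok]
  vy <- var(y)
  if (vy == 0) stop("Var(y) is zero; explained variance undefined")
  apply(ytilde[ok, , drop = FALSE], 2, function(p) 1 - var(y - p) / vy)
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half; R-hat compares within- to between-chain
#' variance. Values above ~1.05 flag non-convergence.
#'
#' @param samples a `posterior_samples` object, or a draws matrix with a
#'   `chain` vector.
#' @param chain chain id per row (when `samples` is a matrix).
#' @return named vector of R-hat values per parameter.
#' @export
rhat <- function(samples, chain = NULL) {
  if (inherits(samples, "posterior_samples")) {
    draws <- samples$draws
    chain <- samples$chain
  } else draws <- as.matrix(samples)
  if (length(unique(chain)) < 1 || is.null(chain))
    stop("chain ids required")
  sid <- stats::ave(seq_along(chain), chain, FUN = function(ix) {
    h <- ceiling(length(ix) / 2)
    rep(1:2, c(h, length(ix) - h))
  })
  grp <- interaction(chain, sid, drop = TRUE)
  if (nlevels(grp) < 2) stop("need at least 2 chains (or splittable draws)")
  apply(draws, 2, function(x) {
    xs <- split(x, grp)
    m <- lengths(xs)
    if (min(m) < 2) return(NA_real_)
    n <- min(m)
    xs <- lapply(xs, function(v) v[seq_len(n)])
    means <- vapply(xs, mean, 0)
    vars <- vapply(xs, var, 0)
    Wv <- mean(vars)
    Bv <- n * var(means)
    if (Wv == 0) return(1)
    sqrt(((n - 1) / n * Wv + Bv / n) / Wv)
  })
}

#' Posterior percentiles
#'
#' 5/25/50/75/95 percentiles per column, mirroring the boxplot convention
#' used for reporting.
#'
#' @param draws matrix of draws (columns = parameters or metrics).
#' @return matrix with one row per percentile.
#' @export
posterior_percentiles <- function(draws) {
  apply(as.matrix(draws), 2, quantile,
        probs = c(0.05, 0.25, 0.5, 0.75, 0.95), names = TRUE, na.rm = TRUE)
}
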