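#' Default prior hyperparameters
#'
#' Weakly informative, scale-matched priors used for all models (the
#' per-parameter mapping is built by the model fit constructors):
#' log-normal (median `rate_median` 1/h, sdlog `rate_sdlog`) for positive
#' rate constants; half-normal (SD `scale_sd`) for meal heights, circadian
#' amplitudes, diffusion intensities and observation-noise SDs; Normal for
#' baseline levels; flat circular for peak times (the likelihood is 24-h
#' periodic in the phase); Normal(0, `coupling_sd`) for the unconstrained
#' couplings; uniform on (-1, 1) for the HR-HRV noise correlation.
#'
#' @param rate_median median of rate priors, 1/h.
#' @param rate_sdlog log-scale SD of rate priors.
#' @param scale_sd SD of half-normal priors for scale-type parameters.
#' @param a0_mean,a0_sd Normal prior for the glucose baseline, mmol/L.
#' @param a0_norm_sd Normal(0, .) prior SD for normalized-channel baselines.
#' @param coupling_sd SD of the Normal priors on couplings C5*.
#' @return list of hyperparameters.
#' @export
default_priors <- function(rate_median = 0.5, rate_sdlog = 1, scale_sd = 2,
                           a0_mean = 5, a0_sd = 2, a0_norm_sd = 2,
                           coupling_sd = 1) {
  list(rate_median = rate_median, rate_sdlog = rate_sdlog,
       scale_sd = scale_sd, a0_mean = a0_mean, a0_sd = a0_sd,
       a0_norm_sd = a0_norm_sd, coupling_sd = coupling_sd)
}

# A prior table is a data.frame with columns: name, type, h1, h2 where type
# is one of "rate" (lognormal on natural = normal on log scale), "hnorm"
# (half-normal on natural, log-transformed, Jacobian included), "norm"
# (identity scale), "flat" (identity scale, improper), "corr" (atanh
# transform, uniform on (-1, 1)). Log-densities and gradients are with
# respect to the unconstrained coordinate.
prior_table <- function(names, types, h1, h2) {
  data.frame(name = names, type = types, h1 = h1, h2 = h2,
             stringsAsFactors = FALSE)
}

prior_logpdf_u <- function(tab, u) {
  stopifnot(length(u) == nrow(tab))
  tot <- 0
  for (i in seq_len(nrow(tab))) {
    tot <- tot + switch(tab$type[i],
      rate = dnorm(u[i], log(tab$h1[i]), tab$h2[i], log = TRUE),
      hnorm = {
        x <- exp(u[i])
        log(2) - 0.5 * log(2 * pi) - log(tab$h1[i]) -
          x^2 / (2 * tab$h1[i]^2) + u[i]
      },
      norm = dnorm(u[i], tab$h1[i], tab$h2[i], log = TRUE),
      flat = 0,
      corr = log1p(-tanh(u[i])^2) - log(2))
  }
  tot
}

prior_grad_u <- function(tab, u) {
  g <- numeric(length(u))
  for (i in seq_len(nrow(tab))) {
    g[i] <- switch(tab$type[i],
      rate = -(u[i] - log(tab$h1[i])) / tab$h2[i]^2,
      hnorm = 1 - exp(2 * u[i]) / tab$h1[i]^2,
      norm = -(u[i] - tab$h1[i]) / tab$h2[i]^2,
      flat = 0,
      corr = -2 * tanh(u[i]))
  }
  g
}
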