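model2_par_names <- function() {
  c("C11", "C21", "C22", "C31", "C33", "D11", "D22", "D33", "rho",
    "A0_act", "A1_act", "phi_act", "A0_hr", "A1_hr", "phi_hr",
    "A0_hrv", "A1_hrv", "phi_hrv", "sigma_act", "sigma_hr", "sigma_hrv")
}

model2_prior_table <- function(priors = default_priors()) {
  nm <- model2_par_names()
  type <- c(rep("rate", 5), rep("hnorm", 3), "corr",
            rep(c("norm", "hnorm", "flat"), 3), rep("hnorm", 3))
  h1 <- c(rep(priors$rate_median, 5), rep(priors$scale_sd, 3), NA,
          rep(c(0, priors$scale_sd, NA), 3), rep(priors$scale_sd, 3))
  h2 <- c(rep(priors$rate_sdlog, 5), rep(NA, 3), NA,
          rep(c(priors$a0_norm_sd, NA, NA), 3), rep(NA, 3))
  prior_table(nm, type, h1, h2)
}

# unconstrained vector <-> cardio_params
cardio_pack <- function(p) {
  c(log(c(p$C11, p$C21, p$C22, p$C31, p$C33)),
    log(pmax(c(p$D11, p$D22, p$D33), 1e-12)), atanh(p$rho),
    p$circ$act[1], log(max(p$circ$act[2], 1e-12)), p$circ$act[3],
    p$circ$hr[1], log(max(p$circ$hr[2], 1e-12)), p$circ$hr[3],
    p$circ$hrv[1], log(max(p$circ$hrv[2], 1e-12)), p$circ$hrv[3],
    log(p$sigma))
}

cardio_unpack <- function(u) {
  cardio_params(C11 = exp(u[1]), C21 = exp(u[2]), C22 = exp(u[3]),
                C31 = exp(u[4]), C33 = exp(u[5]),
                D11 = exp(u[6]), D22 = exp(u[7]), D33 = exp(u[8]),
                rho = tanh(u[9]),
                circ = list(act = c(u[10], exp(u[11]), u[12] %% 24),
                            hr = c(u[13], exp(u[14]), u[15] %% 24),
                            hrv = c(u[16], exp(u[17]), u[18] %% 24)),
                sigma = exp(u[19:21]))
}

model2_objective <- function(record, priors = default_priors()) {
  cd <- cardio_data(record)
  tab <- model2_prior_table(priors)
  loglik_u <- function(u) {
    p <- tryCatch(cardio_unpack(u), error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    tryCatch(model2_loglik(p, record), error = function(e) -Inf)
  }
  logpost <- function(u) {
    ll <- loglik_u(u)
    if (!is.finite(ll)) return(-Inf)
    ll + prior_logpdf_u(tab, u)
  }
  init <- cardio_pack(cardio_params(
    C11 = 1, C21 = 1, C22 = 1, C31 = 1, C33 = 1, D11 = 1, D22 = 1,
    D33 = 1, rho = 0,
    circ = list(act = c(0, 0.3, 14), hr = c(0, 0.3, 16),
                hrv = c(0, 0.3, 4)),
    sigma = c(0.5, 0.5, 0.5)))
  list(logpost = logpost, loglik_u = loglik_u, init = init,
       par_names = model2_par_names(),
       n_obs = sum(is.finite(cd$y)), prior = tab)
}

#' Fit the activity/HR/HRV model
#'
#' MAP estimation (BFGS), optionally followed by two-stage HMC with
#' finite-difference gradients. The MAP (or posterior-mean) parameters are
#' what Model 3 locks.
#'
#' @param record a [participant_record()] with SD-normalized activity, HR
#'   and HRV (RMSSD^-1) on a common grid.
#' @param priors a [default_priors()] list.
#' @param config an [hmc_config()], or `NULL` for MAP only.
#' @return list with `map` ([cardio_params()]), MAP value, and (when
#'   sampled) `posterior_samples`, natural-scale percentiles and the
#'   posterior-mean parameters `post_mean`.
#' @export
fit_model2 <- function(record, priors = default_priors(), config = NULL) {
  obj <- model2_objective(record, priors)
  map <- map_estimate(obj$logpost, obj$init, maxit = 400)
  out <- list(map = cardio_unpack(map$par), map_u = map$par,
              logpost = map$value, n_obs = obj$n_obs,
              par_names = obj$par_names)
  if (!is.null(config)) {
    grad <- function(u) num_grad(obj$logpost, u)
    samp <- hmc_sample(obj$logpost, grad, map$par, config,
                       par_names = obj$par_names)
    out$samples <- samp
    out$post_mean <- cardio_unpack(colMeans(samp$draws))
    nat <- samp$draws
    nat[, c(1:8, 11, 14, 17, 19:21)] <-
      exp(samp$draws[, c(1:8, 11, 14, 17, 19:21)])
    nat[, 9] <- tanh(samp$draws[, 9])
    nat[, c(12, 15, 18)] <- samp$draws[, c(12, 15, 18)] %% 24
    out$percentiles <- posterior_percentiles(nat)
  } else {
    out$post_mean <- out$map
  }
  out
}

#' Export a Model-2 fit as JSON
#'
#' Posterior-mean (or MAP) parameters and the explained-variance table.
#'
#' @param fit result of [fit_model2()].
#' @param record the fitted [participant_record()].
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
model2_report_json <- function(fit, record, path = NULL) {
  pm <- fit$post_mean
  out <- list(model = "cardio",
              params = list(C11 = pm$C11, C21 = pm$C21, C22 = pm$C22,
                            C31 = pm$C31, C33 = pm$C33, D11 = pm$D11,
                            D22 = pm$D22, D33 = pm$D33, rho = pm$rho,
                            circ = pm$circ, sigma = pm$sigma),
              explained_variance = as.list(
                cardio_variance_table(pm, record)),
              n_obs = fit$n_obs)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Rebuild cardio parameters from a Model-2 JSON report
#' @param path report path.
#' @return a [cardio_params()].
#' @export
cardio_params_from_report <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- js$params
  cardio_params(C11 = p$C11, C21 = p$C21, C22 = p$C22, C31 = p$C31,
                C33 = p$C33, D11 = p$D11, D22 = p$D22, D33 = p$D33,
                rho = p$rho,
                circ = list(act = as.numeric(p$circ$act),
                            hr = as.numeric(p$circ$hr),
                            hrv = as.numeric(p$circ$hrv)),
                sigma = as.numeric(p$sigma))
}
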