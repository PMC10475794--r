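model1_par_names <- function(labels, circadian) {
  base <- c("A11", "A12", "A21", "A22", "B22", "sigma", "A0")
  if (circadian) base <- c(base, "A1", "phi")
  c(base, if (length(labels)) paste0("h_", labels))
}

model1_prior_table <- function(labels, circadian, priors = default_priors()) {
  nm <- model1_par_names(labels, circadian)
  type <- c(rep("rate", 4), "hnorm", "hnorm", "norm")
  h1 <- c(rep(priors$rate_median, 4), priors$scale_sd, priors$scale_sd,
          priors$a0_mean)
  h2 <- c(rep(priors$rate_sdlog, 4), NA, NA, priors$a0_sd)
  if (circadian) {
    type <- c(type, "hnorm", "flat")
    h1 <- c(h1, priors$scale_sd, NA)
    h2 <- c(h2, NA, NA)
  }
  if (length(labels)) {
    type <- c(type, rep("hnorm", length(labels)))
    h1 <- c(h1, rep(priors$scale_sd, length(labels)))
    h2 <- c(h2, rep(NA, length(labels)))
  }
  prior_table(nm, type, h1, h2)
}

# posterior building blocks for Model 1 on a participant record
model1_objective <- function(record, circadian = TRUE,
                             priors = default_priors()) {
  g <- record$series$glucose
  if (is.null(g)) stop("record has no glucose series")
  meals <- record$meals
  labels <- names(unique_meal_labels(meals))
  L <- length(labels)
  tab <- model1_prior_table(labels, circadian, priors)
  times <- g$times
  yv <- ifelse(g$missing, 0, g$values)
  obs <- as.integer(!g$missing)
  mt <- meals$times
  ml <- meal_label_index(meals)
  if (is.null(ml)) ml <- integer()
  logpost <- function(u) {
    ll <- cpp_model1_loglik_u(u, L, times, yv, obs, mt, ml, circadian)
    if (!is.finite(ll)) return(-Inf)
    ll + prior_logpdf_u(tab, u)
  }
  grad <- function(u) {
    gl <- cpp_model1_grad_u(u, L, times, yv, obs, mt, ml, circadian)
    gl$grad + prior_grad_u(tab, u)
  }
  loglik_u <- function(u) cpp_model1_loglik_u(u, L, times, yv, obs, mt, ml,
                                              circadian)
  ob <- g$values[!g$missing]
  init <- c(log(c(1, 1, 1, 1, 0.05, max(0.05, 0.4 * sd(ob)))),
            quantile(ob, 0.2, names = FALSE))
  if (circadian) init <- c(init, log(0.5), 15)
  init <- c(init, rep(log(1), L))
  list(logpost = logpost, grad = grad, loglik_u = loglik_u, init = init,
       labels = labels, circadian = circadian, n_obs = sum(obs),
       par_names = model1_par_names(labels, circadian), prior = tab)
}

#' Fit the glucose model to a participant record
#'
#' MAP initialisation (BFGS) followed by two-stage HMC. Returns the draws on
#' the natural scale, derived-metric posteriors (half-life, damping
#' coefficient, mean meal height, circadian amplitude and peak time),
#' posterior percentiles, BIC at the MAP, and convergence diagnostics.
#'
#' @param record a [participant_record()] with a (detrended) glucose series.
#' @param circadian fit the circadian baseline? `FALSE` gives the reduced
#'   variant used for BIC comparison (2 fewer parameters).
#' @param priors a [default_priors()] list.
#' @param config an [hmc_config()].
#' @param ev_draws number of thinned draws used for explained-variance
#'   posteriors (0 skips them).
#' @return object of class `model1_fit`.
#' @export
fit_model1 <- function(record, circadian = TRUE, priors = default_priors(),
                       config = hmc_config(), ev_draws = 200) {
  obj <- model1_objective(record, circadian, priors)
  map <- map_estimate(obj$logpost, obj$init, obj$grad)
  samp <- hmc_sample(obj$logpost, obj$grad, map$par, config,
                     par_names = obj$par_names)
  map_params <- glucose_unpack(map$par, obj$labels, circadian)
  nat <- model1_natural_draws(samp$draws, obj$labels, circadian)
  met <- model1_metric_draws(samp$draws, obj$labels, circadian,
                             record$meals)
  k <- length(obj$par_names)
  b <- bic(obj$loglik_u(map$par), k, obj$n_obs)
  ev <- NULL
  if (ev_draws > 0) {
    idx <- unique(round(seq(1, nrow(samp$draws),
                            length.out = min(ev_draws, nrow(samp$draws)))))
    g <- record$series$glucose
    y <- ifelse(g$missing, NA_real_, g$values)
    # EV is invariant to additive constants, so r + A0 suffices for the
    # meal-only decomposition
    pm <- vapply(idx, function(i) {
      p <- glucose_unpack(samp$draws[i, ], obj$labels, circadian)
      model1_mean(p, record$meals, g$times, circadian = FALSE)
    }, numeric(length(y)))
    pmc <- vapply(idx, function(i) {
      p <- glucose_unpack(samp$draws[i, ], obj$labels, circadian)
      model1_mean(p, record$meals, g$times, circadian = circadian)
    }, numeric(length(y)))
    ev <- list(meals_only = explained_variance(y, pm),
               meals_circadian = explained_variance(y, pmc))
  }
  rh <- if (config$n_chains >= 2) rhat(samp) else NULL
  structure(list(map = map_params, map_u = map$par, samples = samp,
                 natural_draws = nat, metric_draws = met,
                 percentiles = posterior_percentiles(nat),
                 metric_percentiles = posterior_percentiles(met),
                 bic = b, k = k, n_obs = obj$n_obs,
                 loglik_map = obj$loglik_u(map$par),
                 explained_variance = ev, rhat = rh,
                 circadian = circadian, labels = obj$labels),
            class = "model1_fit")
}

#' @export
print.model1_fit <- function(x, ...) {
  cat(sprintf("<model1_fit: %s, %d draws, BIC %.1f>\n",
              if (x$circadian) "circadian" else "no-circadian",
              nrow(x$samples$draws), x$bic))
  print(round(x$metric_percentiles, 3))
  invisible(x)
}

# draws on the natural scale (columns named like par_names)
model1_natural_draws <- function(draws_u, labels, circadian) {
  nat <- draws_u
  nat[, 1:6] <- exp(draws_u[, 1:6])
  if (circadian) {
    nat[, 8] <- exp(draws_u[, 8])
    nat[, 9] <- draws_u[, 9] %% 24
    off <- 9
  } else off <- 7
  L <- length(labels)
  if (L) nat[, off + seq_len(L)] <- exp(draws_u[, off + seq_len(L)])
  nat
}

# derived metrics per posterior draw
model1_metric_draws <- function(draws_u, labels, circadian, meals) {
  n <- nrow(draws_u)
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("half_life", "damping",
                                        "mean_meal_height",
                                        "circadian_amplitude",
                                        "circadian_peak_time")))
  for (i in seq_len(n)) {
    p <- glucose_unpack(draws_u[i, ], labels, circadian)
    out[i, 1] <- tryCatch(half_life(p), error = function(e) NA_real_)
    out[i, 2] <- damping_coefficient(glucose_W(p))
    out[i, 3] <- if (length(meals)) mean(unname(p$heights[meals$labels]))
                 else NA_real_
    out[i, 4] <- p$A1
    out[i, 5] <- p$phi %% 24
  }
  out
}

#' BIC comparison of the circadian vs no-circadian glucose model
#'
#' Fits both variants by MAP only (BIC needs the likelihood at the
#' estimate, not posterior draws) and applies the `2 ln(10)` cutoff.
#'
#' @param record a [participant_record()].
#' @param priors a [default_priors()] list.
#' @return list with both BICs, their difference and the verdict.
#' @export
model1_bic_comparison <- function(record, priors = default_priors()) {
  of <- model1_objective(record, TRUE, priors)
  or <- model1_objective(record, FALSE, priors)
  mf <- map_estimate(of$logpost, of$init, of$grad)
  mr <- map_estimate(or$logpost, or$init, or$grad)
  bf <- bic(of$loglik_u(mf$par), length(of$par_names), of$n_obs)
  br <- bic(or$loglik_u(mr$par), length(or$par_names), or$n_obs)
  list(bic_full = bf, bic_reduced = br, delta = br - bf,
       verdict = compare_bic(bf, br))
}

#' Export a Model-1 fit as JSON
#'
#' Parameter and derived-metric posterior percentiles (5/25/50/75/95),
#' MAP values, BIC and convergence diagnostics.
#'
#' @param fit a `model1_fit`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
model1_report_json <- function(fit, path = NULL) {
  pct_df <- function(m) {
    data.frame(name = colnames(m), p5 = m[1, ], p25 = m[2, ], p50 = m[3, ],
               p75 = m[4, ], p95 = m[5, ], row.names = NULL)
  }
  out <- list(model = if (fit$circadian) "glucose_circadian" else
                "glucose_no_circadian",
              map = unclass(fit$map),
              parameter_percentiles = pct_df(fit$percentiles),
              metric_percentiles = pct_df(fit$metric_percentiles),
              bic = fit$bic, k = fit$k, n_obs = fit$n_obs,
              loglik_map = fit$loglik_map,
              accept_rate = fit$samples$accept_rate,
              rhat = fit$rhat)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
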