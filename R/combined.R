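#' Combined model parameters
#'
#' Five-dimensional model stitching the activity/HR/HRV block (parameters
#' locked to their Model-2 posterior means during fitting) to the glucose
#' block, with three unconstrained couplings `C51, C52, C53` carrying the
#' effect of activity, HR and HRV into the observed glucose component
#' (state row 5, matching the coefficient subscripts).
#'
#' @param cardio a [cardio_params()] (locked during Model-3 fitting).
#' @param glucose a [glucose_params()].
#' @param C5 length-3 numeric couplings `(C51, C52, C53)`, any sign.
#' @return object of class `combined_params`.
#' @export
combined_params <- function(cardio, glucose, C5 = c(0, 0, 0)) {
  stopifnot(inherits(cardio, "cardio_params"),
            inherits(glucose, "glucose_params"),
            length(C5) == 3, all(is.finite(C5)))
  structure(list(cardio = cardio, glucose = glucose, C5 = as.numeric(C5)),
            class = "combined_params")
}

combined_W <- function(p) {
  W <- matrix(0, 5, 5)
  W[1:3, 1:3] <- cardio_W(p$cardio)
  W[4:5, 4:5] <- glucose_W(p$glucose)
  W[5, 1:3] <- p$C5
  W
}

combined_Q <- function(p) {
  Q <- matrix(0, 5, 5)
  Q[1:3, 1:3] <- cardio_Q(p$cardio)
  Q[5, 5] <- p$glucose$B22
  Q
}

#' LTI system of the combined model
#'
#' @param params a [combined_params()].
#' @return an [lti_system()] with `d = 5`; errors if the assembled drift is
#'   unstable.
#' @export
build_combined_system <- function(params) {
  tryCatch(lti_system(combined_W(params), combined_Q(params)),
           error = function(e)
             stop("combined drift matrix unstable or invalid: ",
                  conditionMessage(e)))
}

# combined-model observation pieces on the CGM grid: aux channels
# aggregated to the grid by interval means
combined_H <- function() {
  H <- matrix(0, 4, 5)
  H[1, 1] <- H[2, 2] <- H[3, 3] <- H[4, 5] <- 1
  H
}

#' Aggregate a series to a coarser grid by interval means
#'
#' Each target grid point `t_k` receives the mean of source observations in
#' `(t_k - dt, t_k]`; intervals with no observed source points are `NA`.
#'
#' @param series a [sensor_series()].
#' @param grid target times (hours), regular spacing.
#' @return numeric vector on `grid` with `NA` where no data fall.
#' @export
aggregate_to_grid <- function(series, grid) {
  dt <- if (length(grid) > 1) min(diff(grid)) else Inf
  ob <- observed(series)
  # assign each obs to the first grid point >= its time (within one step)
  bin <- findInterval(ob$times - 1e-9, grid) + 1L
  bin[bin > length(grid)] <- NA
  ok <- !is.na(bin) & (grid[bin] - ob$times) < dt + 1e-9
  out <- rep(NA_real_, length(grid))
  if (any(ok)) {
    agg <- tapply(ob$values[ok], bin[ok], mean)
    out[as.integer(names(agg))] <- agg
  }
  out
}

# CGM grid + 4-channel data matrix (act, hr, hrv normalized; glucose
# mmol/L); aux series must already be SD-normalized
combined_data <- function(record) {
  g <- record$series$glucose
  if (is.null(g)) stop("record has no glucose series")
  grid <- g$times
  aux <- vapply(cardio_channels, function(ch) {
    s <- record$series[[ch]]
    if (is.null(s)) stop("record needs channel ", ch)
    aggregate_to_grid(s, grid)
  }, numeric(length(grid)))
  y <- cbind(aux, ifelse(g$missing, NA_real_, g$values))
  colnames(y) <- c(cardio_channels, "glucose")
  list(times = grid, y = y)
}

combined_mean <- function(params, meals, t, circadian = TRUE) {
  cbind(cardio_mean(params$cardio, t),
        model1_mean(params$glucose, meals, t, circadian))
}

#' Exact log-likelihood of the combined model
#'
#' Four observed channels on the CGM grid (aux channels aggregated by
#' interval means), exact Kalman likelihood with per-step missing-channel
#' handling.
#'
#' @param params a [combined_params()].
#' @param record a [participant_record()] with all four channels (aux
#'   SD-normalized, glucose detrended mmol/L).
#' @param circadian include the glucose circadian baseline?
#' @return log-likelihood (scalar).
#' @export
model3_loglik <- function(params, record, circadian = TRUE) {
  cd <- combined_data(record)
  sys <- build_combined_system(params)
  kalman_filter(sys, cd$times, cd$y, H = combined_H(),
                m = combined_mean(params, record$meals, cd$times, circadian),
                R = c(params$cardio$sigma^2, params$glucose$sigma^2))$loglik
}

#' Weighted sum of the auxiliary channels
#'
#' `C51 * activity + C52 * HR + C53 * HRV` on the CGM grid, the model's
#' net auxiliary drive on glucose. With `impute = TRUE`, missing aux values
#' are filled with Model-2 smoothed estimates (circadian mean plus smoothed
#' latent state).
#'
#' @param params a [combined_params()].
#' @param record a [participant_record()].
#' @param impute fill missing aux values from the Model-2 smoother?
#' @return list with `times` and `sum` (NA where aux is missing and
#'   imputation is off).
#' @export
weighted_aux_sum <- function(params, record, impute = FALSE) {
  cd <- combined_data(record)
  aux <- cd$y[, 1:3, drop = FALSE]
  if (impute) {
    cda <- cardio_data(record)
    sys <- build_cardio_system(params$cardio)
    m <- cardio_mean(params$cardio, cda$times)
    sm <- kalman_filter(sys, cda$times, cda$y, H = diag(3), m = m,
                        R = params$cardio$sigma^2, keep = TRUE,
                        smooth = TRUE)
    fitted <- m + sm$smooth_mean
    for (j in 1:3) {
      s <- record$series[[cardio_channels[j]]]
      filled <- s
      filled$values <- fitted[, j]
      filled$missing <- rep(FALSE, length(s$times))
      agg <- aggregate_to_grid(filled, cd$times)
      aux[is.na(aux[, j]), j] <- agg[is.na(aux[, j])]
    }
  }
  # channels with zero coefficient contribute exactly 0, even when missing
  contrib <- sweep(aux, 2, params$C5, `*`)
  contrib[, params$C5 == 0] <- 0
  list(times = cd$times, sum = rowSums(contrib))
}

#' Cross-correlation between two series on a common grid
#'
#' Pearson correlation at integer-grid lags in `[-max_lag, max_lag]` hours;
#' pairs with missing values are dropped per lag, and lags with fewer than
#' 3 overlapping pairs are `NA`. A peak at a positive lag means `y` is
#' delayed relative to `x` by that many hours.
#'
#' @param x,y numeric vectors on a common regular grid (`NA` = missing).
#' @param dt grid step in hours.
#' @param max_lag maximum lag in hours.
#' @return data.frame with `lag_hours` and `correlation`, plus attribute
#'   `peak_lag` (lag of maximum correlation).
#' @export
cross_correlation <- function(x, y, dt, max_lag = 12) {
  stopifnot(length(x) == length(y), dt > 0)
  L <- floor(max_lag / dt)
  lags <- -L:L
  n <- length(x)
  cc <- vapply(lags, function(l) {
    if (l >= 0) { xi <- x[seq_len(n - l)]
                  yi <- y[seq_len(n - l) + l] }
    else        { xi <- x[seq_len(n + l) - l]
                  yi <- y[seq_len(n + l)] }
    ok <- is.finite(xi) & is.finite(yi)
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(xi[ok], yi[ok]))
  }, 0)
  out <- data.frame(lag_hours = lags * dt, correlation = cc)
  attr(out, "peak_lag") <- out$lag_hours[which.max(cc)]
  out
}

#' Refit the coupling of a single auxiliary input
#'
#' Simpler model variant with only one of activity/HR/HRV feeding glucose
#' (the other two couplings pinned at 0); the glucose parameters and the
#' remaining coupling are re-estimated by MAP (optionally followed by HMC
#' through [fit_model3()]). Used for sign-robustness checks.
#'
#' @param params a [combined_params()] supplying the locked cardio block
#'   and starting values.
#' @param record a [participant_record()].
#' @param input one of `"activity"`, `"hr"`, `"hrv"`.
#' @param priors a [default_priors()] list.
#' @return list with the refitted `coupling`, full `params` at the MAP and
#'   the MAP log posterior.
#' @export
single_input_variant <- function(params, record, input,
                                 priors = default_priors()) {
  input <- match.arg(input, cardio_channels)
  free <- match(input, cardio_channels)
  obj <- model3_objective(record, params$cardio, free_couplings = free,
                          priors = priors)
  map <- map_estimate(obj$logpost, obj$init, maxit = 300)
  pp <- obj$unpack(map$par)
  list(coupling = pp$C5[free], params = pp, logpost = map$value)
}

# Model-3 posterior building blocks: glucose parameters + the free
# couplings (cardio block locked). free_couplings: indices in 1:3.
model3_objective <- function(record, cardio_locked,
                             free_couplings = 1:3,
                             priors = default_priors(), circadian = TRUE) {
  labels <- names(unique_meal_labels(record$meals))
  tab1 <- model1_prior_table(labels, circadian, priors)
  nC <- length(free_couplings)
  tab <- rbind(tab1, prior_table(paste0("C5", free_couplings),
                                 rep("norm", nC), rep(0, nC),
                                 rep(priors$coupling_sd, nC)))
  cd <- combined_data(record)
  H <- combined_H()
  R <- c(cardio_locked$sigma^2, NA)
  nu1 <- nrow(tab1)
  unpack <- function(u) {
    gp <- glucose_unpack(u[seq_len(nu1)], labels, circadian)
    C5 <- numeric(3)
    C5[free_couplings] <- u[nu1 + seq_len(nC)]
    combined_params(cardio_locked, gp, C5)
  }
  loglik_u <- function(u) {
    p <- tryCatch(unpack(u), error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    W <- combined_W(p)
    if (max(Re(eigen(W, only.values = TRUE)$values)) >= -1e-10) return(-Inf)
    tryCatch(model3_loglik(p, record, circadian), error = function(e) -Inf)
  }
  logpost <- function(u) {
    ll <- loglik_u(u)
    if (!is.finite(ll)) return(-Inf)
    ll + prior_logpdf_u(tab, u)
  }
  ob1 <- model1_objective(record, circadian, priors)
  init <- c(ob1$init, rep(0, nC))
  list(logpost = logpost, loglik_u = loglik_u, unpack = unpack, init = init,
       par_names = c(ob1$par_names, paste0("C5", free_couplings)),
       n_obs = sum(is.finite(cd$y)), prior = tab)
}

#' Fit the combined model (cardio block locked)
#'
#' MAP then HMC over the glucose parameters and the free couplings, with
#' the activity/HR/HRV block held at the supplied (posterior-mean) values.
#'
#' @param record a [participant_record()].
#' @param cardio_locked a [cardio_params()] (e.g. Model-2 posterior means).
#' @param free_couplings indices in `1:3` of couplings to estimate.
#' @param priors a [default_priors()] list.
#' @param config an [hmc_config()].
#' @return list with MAP parameters, `posterior_samples` (unconstrained),
#'   natural-scale coupling draws and percentiles.
#' @export
fit_model3 <- function(record, cardio_locked, free_couplings = 1:3,
                       priors = default_priors(), config = hmc_config()) {
  obj <- model3_objective(record, cardio_locked, free_couplings, priors)
  grad <- function(u) num_grad(obj$logpost, u)
  map <- map_estimate(obj$logpost, obj$init, maxit = 300)
  samp <- hmc_sample(obj$logpost, grad, map$par, config,
                     par_names = obj$par_names)
  nC <- length(free_couplings)
  cidx <- ncol(samp$draws) - nC + seq_len(nC)
  cdraws <- samp$draws[, cidx, drop = FALSE]
  list(map = obj$unpack(map$par), samples = samp,
       coupling_draws = cdraws,
       coupling_percentiles = posterior_percentiles(cdraws),
       n_obs = obj$n_obs)
}

num_grad <- function(f, u, h = 1e-5) {
  f0 <- f(u)
  vapply(seq_along(u), function(i) {
    up <- u; up[i] <- u[i] + h
    um <- u; um[i] <- u[i] - h
    (f(up) - f(um)) / (2 * h)
  }, 0)
}

#' Glucose explained-variance decomposition
#'
#' Explained variance of the glucose series using (i) the meal + circadian
#' prediction `r + g` alone and (ii) additionally the expected auxiliary
#' contribution `E[x_GLUC2 | observed aux channels]` from the coupled
#' model, per parameter draw, summarized at 5/50/95 percentiles.
#'
#' @param params a [combined_params()], or a list of them (one per draw).
#' @param record a [participant_record()].
#' @return list with per-draw values and `percentiles` (rows = 5/50/95).
#' @export
glucose_variance_decomposition <- function(params, record) {
  if (inherits(params, "combined_params")) params <- list(params)
  cd <- combined_data(record)
  yg <- cd$y[, 4]
  res <- vapply(params, function(p) {
    m <- combined_mean(p, record$meals, cd$times)
    base <- m[, 4]
    yaux <- cd$y
    yaux[, 4] <- NA
    sys <- build_combined_system(p)
    sm <- kalman_filter(sys, cd$times, yaux, H = combined_H(), m = m,
                        R = c(p$cardio$sigma^2, p$glucose$sigma^2),
                        keep = TRUE, smooth = TRUE)
    withaux <- base + sm$smooth_mean[, 5]
    c(explained_variance(yg, base), explained_variance(yg, withaux))
  }, numeric(2))
  pct <- apply(res, 1, quantile, probs = c(0.05, 0.5, 0.95))
  colnames(pct) <- c("meals_circadian", "plus_aux")
  list(draws = t(res), percentiles = pct)
}
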