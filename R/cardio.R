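#' Physical and heart activity model parameters
#'
#' Three-dimensional model of SD-normalized activity, HR and HRV (RMSSD^-1):
#' lower-triangular drift
#' `W = [-C11 0 0; C21 -C22 0; C31 0 -C33]` (activity drives HR and HRV),
#' diffusion `Q` with HR-HRV off-diagonal `rho * sqrt(D22 * D33)` so that
#' `rho` is the correlation of the HR and HRV fluctuations, independent
#' per-channel circadian baselines of the same sinusoid family as the
#' glucose model, and diagonal observation noise.
#'
#' @param C11,C22,C33 positive relaxation rates (1/h).
#' @param C21,C31 positive activity-to-HR and activity-to-HRV couplings.
#' @param D11,D22,D33 nonnegative diffusion intensities.
#' @param rho HR-HRV noise correlation in (-1, 1).
#' @param circ named list of circadian triples `c(A0, A1, phi)` for
#'   `act`, `hr`, `hrv` (normalized units; `phi` in clock hours).
#' @param sigma length-3 positive observation-noise SDs (act, hr, hrv).
#' @return object of class `cardio_params`.
#' @export
cardio_params <- function(C11, C21, C22, C31, C33, D11, D22, D33, rho = 0,
                          circ = list(act = c(0, 0, 12), hr = c(0, 0, 15),
                                      hrv = c(0, 0, 3)),
                          sigma = c(0.3, 0.3, 0.3)) {
  # diagonal relaxation rates strictly positive (stability); the
  # activity couplings may sit at the boundary 0 (decoupled limit)
  stopifnot(C11 > 0, C21 >= 0, C22 > 0, C31 >= 0, C33 > 0,
            D11 >= 0, D22 >= 0, D33 >= 0, length(sigma) == 3,
            all(sigma > 0), all(c("act", "hr", "hrv") %in% names(circ)))
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  structure(list(C11 = C11, C21 = C21, C22 = C22, C31 = C31, C33 = C33,
                 D11 = D11, D22 = D22, D33 = D33, rho = rho, circ = circ,
                 sigma = sigma),
            class = "cardio_params")
}

cardio_W <- function(p) {
  matrix(c(-p$C11, p$C21, p$C31,
           0, -p$C22, 0,
           0, 0, -p$C33), 3, 3)
}

cardio_Q <- function(p) {
  od <- p$rho * sqrt(p$D22 * p$D33)
  Q <- diag(c(p$D11, p$D22, p$D33))
  Q[2, 3] <- Q[3, 2] <- od
  Q
}

#' LTI system of the activity/HR/HRV model
#' @param params a [cardio_params()].
#' @return an [lti_system()] with `d = 3`.
#' @export
build_cardio_system <- function(params) {
  lti_system(cardio_W(params), cardio_Q(params))
}

# T x 3 circadian baselines (act, hr, hrv)
cardio_mean <- function(params, t) {
  cbind(circadian_baseline(params$circ$act[1], params$circ$act[2],
                           params$circ$act[3], t),
        circadian_baseline(params$circ$hr[1], params$circ$hr[2],
                           params$circ$hr[3], t),
        circadian_baseline(params$circ$hrv[1], params$circ$hrv[2],
                           params$circ$hrv[3], t))
}

cardio_channels <- c("activity", "hr", "hrv")

# common grid + T x 3 data matrix (NA = missing) from a record; channels
# must share timestamps (the device exports one row per epoch)
cardio_data <- function(record) {
  ss <- record$series[cardio_channels]
  if (any(vapply(ss, is.null, TRUE)))
    stop("record needs activity, hr and hrv series")
  tt <- ss[[1]]$times
  for (s in ss[-1])
    if (length(s$times) != length(tt) || max(abs(s$times - tt)) > 1e-9)
      stop("activity, hr and hrv must share a common time grid")
  y <- vapply(ss, function(s) ifelse(s$missing, NA_real_, s$values),
              numeric(length(tt)))
  list(times = tt, y = y)
}

#' Exact log-likelihood of the activity/HR/HRV model
#'
#' Channels are expected SD-normalized with HRV as RMSSD^-1. Missing
#' channels at a step are handled by row deletion.
#'
#' @param params a [cardio_params()].
#' @param record a [participant_record()] with the three channels on a
#'   common grid.
#' @return log-likelihood (scalar).
#' @export
model2_loglik <- function(params, record) {
  cd <- cardio_data(record)
  sys <- build_cardio_system(params)
  kalman_filter(sys, cd$times, cd$y, H = diag(3),
                m = cardio_mean(params, cd$times),
                R = params$sigma^2)$loglik
}

#' Conditional prediction of one channel from a subset of the others
#'
#' `ytilde(t) = g_target(t) + E[x_target(t) | observations of the included
#' channels]`, computed by fixed-interval smoothing (default) or filtering
#' on the fitted joint model with only the included channels observed. An
#' empty `included` set returns the target's circadian curve.
#'
#' @param params a [cardio_params()].
#' @param record a [participant_record()].
#' @param target channel to predict (`"activity"`, `"hr"`, `"hrv"`).
#' @param included character vector of channels used as evidence (must not
#'   contain `target`).
#' @param method `"smooth"` (default) or `"filter"`.
#' @return list with `times` and `pred`.
#' @export
conditional_prediction <- function(params, record, target,
                                   included = character(),
                                   method = c("smooth", "filter")) {
  method <- match.arg(method)
  target <- match.arg(target, cardio_channels)
  included <- vapply(included, function(ch)
    match.arg(ch, cardio_channels), "")
  if (target %in% included) stop("target must not be in the included set")
  cd <- cardio_data(record)
  ti <- match(target, cardio_channels)
  m <- cardio_mean(params, cd$times)
  if (!length(included))
    return(list(times = cd$times, pred = m[, ti]))
  y <- cd$y
  y[, setdiff(seq_len(3), match(included, cardio_channels))] <- NA
  sys <- build_cardio_system(params)
  res <- kalman_filter(sys, cd$times, y, H = diag(3), m = m,
                       R = params$sigma^2, keep = TRUE,
                       smooth = method == "smooth")
  lat <- if (method == "smooth") res$smooth_mean else res$filt_mean
  list(times = cd$times, pred = m[, ti] + lat[, ti])
}

#' Explained-variance table for HR and HRV predictions
#'
#' Explained variance of HR given circadian rhythm alone and circadian +
#' activity, and of HRV given circadian, circadian + activity, and
#' circadian + activity + HR.
#'
#' @param params a [cardio_params()] (or a list of draws; each row
#'   summarized by the caller).
#' @param record a [participant_record()].
#' @param method passed to [conditional_prediction()].
#' @return named numeric vector of explained variances.
#' @export
cardio_variance_table <- function(params, record,
                                  method = c("smooth", "filter")) {
  method <- match.arg(method)
  cd <- cardio_data(record)
  ev <- function(target, included) {
    p <- conditional_prediction(params, record, target, included, method)
    explained_variance(cd$y[, match(target, cardio_channels)], p$pred)
  }
  c(hr_circadian = ev("hr", character()),
    hr_circadian_activity = ev("hr", "activity"),
    hrv_circadian = ev("hrv", character()),
    hrv_circadian_activity = ev("hrv", "activity"),
    hrv_circadian_activity_hr = ev("hrv", c("activity", "hr")))
}
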