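#' Remove long-term CGM trends with a Gaussian-process smoother
#'
#' Fits a zero-mean Gaussian process with squared-exponential kernel
#' `k(t, t') = exp(-(t - t')^2 / (2 l^2))` to the mean-centred glucose
#' series and subtracts the posterior-mean trend, restoring the grand mean
#' so that the detrended series keeps its interpretable mmol/L level. With
#' the default length scale of 48 h the trend absorbs multi-day drift
#' (sensor aging, lifestyle shifts) while leaving 24-h structure intact.
#'
#' @param glucose a glucose [sensor_series()] with at least 2 observed points.
#' @param l kernel length scale in hours (default 48).
#' @param noise_sd observation-noise SD (mmol/L) of the GP fit; default is
#'   `sd(diff(values))/sqrt(2)`, a scale-matched estimate that stops the
#'   trend from interpolating measurement noise.
#' @return list with `trend` (on the full grid), `detrended`
#'   ([sensor_series()]), `l`, `noise_sd` and the grand `mean`.
#' @export
gp_detrend <- function(glucose, l = 48, noise_sd = NULL) {
  stopifnot(inherits(glucose, "sensor_series"), l > 0)
  ob <- observed(glucose)
  n <- length(ob$times)
  if (n < 2) stop("need at least 2 observed points")
  if (is.null(noise_sd)) noise_sd <- sd(diff(ob$values)) / sqrt(2)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    noise_sd <- max(1e-3, 0.05 * sd(ob$values))
  mu <- mean(ob$values)
  yc <- ob$values - mu
  K <- exp(-outer(ob$times, ob$times, "-")^2 / (2 * l^2))
  alpha <- tryCatch(
    solve(K + diag(noise_sd^2, n), yc),
    error = function(e) stop("singular kernel system (", conditionMessage(e),
                             "); increase noise_sd to add jitter"))
  Ks <- exp(-outer(glucose$times, ob$times, "-")^2 / (2 * l^2))
  trend <- drop(Ks %*% alpha)
  vals <- glucose$values - trend
  det <- sensor_series("glucose", glucose$times,
                       ifelse(glucose$missing, NA_real_, vals),
                       missing = glucose$missing)
  list(trend = trend + mu, detrended = det, l = l, noise_sd = noise_sd,
       mean = mu)
}

#' Normalize a series by its sample standard deviation
#'
#' @param series a [sensor_series()] with >= 2 observed values and nonzero
#'   variance.
#' @return list with `series` (normalized) and `sd` (for back-transformation).
#' @export
sd_normalize <- function(series) {
  stopifnot(inherits(series, "sensor_series"))
  v <- observed(series)$values
  if (length(v) < 2) stop("need at least 2 observed values")
  s <- sd(v)
  if (!is.finite(s) || s == 0) stop("zero variance; cannot normalize")
  out <- series
  out$values <- series$values / s
  out$unit <- paste0(series$unit, " (SD units)")
  list(series = out, sd = s)
}

#' Invert an RMSSD series (ms -> ms^-1)
#'
#' The heart-rate-variability channel is modelled as RMSSD^-1; missingness
#' is propagated and applying the inversion twice recovers the input.
#'
#' @param rmssd a [sensor_series()] with positive observed values (ms).
#' @return an `hrv` [sensor_series()] in ms^-1.
#' @export
rmssd_inverse <- function(rmssd) {
  stopifnot(inherits(rmssd, "sensor_series"))
  bad <- !rmssd$missing & rmssd$values <= 0
  if (any(bad))
    stop(sprintf("nonpositive RMSSD value at t = %.4f h",
                 rmssd$times[which(bad)[1]]))
  sensor_series("hrv", rmssd$times,
                ifelse(rmssd$missing, NA_real_, 1 / rmssd$values),
                missing = rmssd$missing,
                unit = if (rmssd$unit == "1/ms") "ms" else "1/ms")
}
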