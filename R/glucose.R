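#' Glucose model parameters
#'
#' Parameters of the two-dimensional glucose model: drift
#' `W = [-A11 -A12; A21 -A22]` (all rates positive, hence stable), process
#' noise `Q = diag(0, B22)` acting on the observed glucose component,
#' per-label meal heights, a 24-h sinusoidal baseline
#' `g(t) = A0 + A1 (1 + cos(w t - w phi)) / 2` (peak value `A0 + A1` at
#' clock hour `phi`, trough `A0`), and observation-noise SD `sigma`.
#'
#' @param A11,A12,A21,A22 positive rate constants (1/h).
#' @param B22 process-noise intensity of the glucose component (>= 0).
#' @param heights named nonnegative vector of meal heights (mmol/L), one per
#'   meal label.
#' @param A0 baseline (trough) glucose, mmol/L.
#' @param A1 circadian amplitude (peak minus trough), mmol/L, >= 0.
#' @param phi circadian peak time, clock hours in `[0, 24)`.
#' @param sigma observation-noise SD, mmol/L, > 0.
#' @return object of class `glucose_params`.
#' @export
glucose_params <- function(A11, A12, A21, A22, B22, heights = numeric(),
                           A0 = 4.5, A1 = 0, phi = 15, sigma = 0.3) {
  stopifnot(A11 > 0, A12 > 0, A21 > 0, A22 > 0, B22 >= 0,
            all(heights >= 0), A1 >= 0, sigma > 0)
  structure(list(A11 = A11, A12 = A12, A21 = A21, A22 = A22, B22 = B22,
                 heights = heights, A0 = A0, A1 = A1, phi = phi %% 24,
                 sigma = sigma),
            class = "glucose_params")
}

glucose_W <- function(p) {
  matrix(c(-p$A11, p$A21, -p$A12, -p$A22), 2, 2)
}

#' LTI system of the glucose model
#' @param params a [glucose_params()].
#' @return an [lti_system()] with `d = 2`.
#' @export
glucose_system <- function(params) {
  lti_system(glucose_W(params), diag(c(0, params$B22)))
}

#' Total meal response on a time grid
#'
#' Each ingestion event perturbs the latent component and produces the
#' deterministic glucose-channel impulse response of the system, rescaled
#' so its maximum equals the event label's meal-height parameter; the total
#' response is the superposition over events (exact by linearity).
#'
#' @param params a [glucose_params()]; `heights` must cover all labels in
#'   `meals`.
#' @param meals a [meal_log()].
#' @param t evaluation time grid (hours).
#' @return numeric vector, `r(t)` in mmol/L.
#' @export
meal_response <- function(params, meals, t) {
  stopifnot(inherits(params, "glucose_params"), inherits(meals, "meal_log"))
  r <- numeric(length(t))
  if (!length(meals)) return(r)
  labs <- unique(meals$labels)
  miss <- setdiff(labs, names(params$heights))
  if (length(miss))
    stop("no meal-height parameter for label(s): ", paste(miss, collapse = ", "))
  pk <- cpp_impulse2_peak(params$A11, params$A12, params$A21, params$A22)
  for (i in seq_along(meals$times)) {
    s <- t - meals$times[i]
    idx <- which(s > 0)
    if (!length(idx)) next
    h <- params$heights[[meals$labels[i]]]
    r[idx] <- r[idx] +
      h * cpp_impulse2(params$A11, params$A12, params$A21, params$A22,
                       s[idx]) / pk$f_peak
  }
  r
}

#' Circadian baseline
#'
#' `g(t) = A0 + A1 (1 + cos(w t - w phi)) / 2` with `w = 2 pi / 24` fixed:
#' peak `A0 + A1` at clock hour `phi`, trough `A0` twelve hours later, mean
#' `A0 + A1/2` over any full day.
#'
#' @param A0 trough level. @param A1 amplitude (peak minus trough).
#' @param phi peak clock hour. @param t times in hours (clock phase is
#'   `t %% 24`).
#' @return numeric vector.
#' @export
circadian_baseline <- function(A0, A1, phi, t) {
  w <- 2 * pi / 24
  A0 + A1 * (1 + cos(w * t - w * phi)) / 2
}

#' Damping coefficient of a 2 x 2 drift matrix
#'
#' `-det(W - I tr(W)/2) / (tr(W)/2)^2`: negative iff the eigenvalues are
#' complex (underdamped, dipping response), positive iff real and distinct
#' (overdamped), zero at a repeated eigenvalue (critical damping).
#'
#' @param W 2 x 2 drift matrix with `tr(W) != 0`.
#' @return dimensionless real number.
#' @export
damping_coefficient <- function(W) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == 2, ncol(W) == 2)
  tr2 <- sum(diag(W)) / 2
  if (tr2 == 0) stop("damping coefficient undefined for tr(W) = 0")
  -det(W - diag(tr2, 2)) / tr2^2
}

#' Glucose response half-life
#'
#' Time for the unit-peak normalized meal response to decay from 1 to
#' 0.5 mmol/L, measured from the response peak, found by bracketing and
#' root refinement to 1e-6 h.
#'
#' @param params a [glucose_params()] (only the four rates are used).
#' @param horizon search horizon after the peak, hours (default 72).
#' @return half-life in hours.
#' @export
half_life <- function(params, horizon = 72) {
  stopifnot(inherits(params, "glucose_params"))
  pk <- cpp_impulse2_peak(params$A11, params$A12, params$A21, params$A22)
  u <- function(s) cpp_impulse2(params$A11, params$A12, params$A21,
                                params$A22, s) / pk$f_peak
  lo <- pk$s_peak
  step <- max(pk$s_peak / 4, 0.05)
  hi <- lo + step
  while (u(hi) > 0.5 && hi < pk$s_peak + horizon) {
    lo <- hi
    hi <- hi + step
    step <- step * 1.5
  }
  if (u(hi) > 0.5)
    stop("response does not reach 0.5 within ", horizon,
         " h after the peak (pathological parameters)")
  root <- uniroot(function(s) u(s) - 0.5, c(lo, hi), tol = 1e-6)$root
  root - pk$s_peak
}

# natural-parameter vector in C++ order
glucose_par_vec <- function(p) {
  c(p$A11, p$A12, p$A21, p$A22, p$B22, p$sigma, p$A0, p$A1, p$phi)
}

# align heights to a meal log's first-occurrence label order
aligned_heights <- function(params, meals) {
  labs <- names(unique_meal_labels(meals))
  if (!length(labs)) return(numeric())
  miss <- setdiff(labs, names(params$heights))
  if (length(miss))
    stop("no meal-height parameter for label(s): ", paste(miss, collapse = ", "))
  unname(params$heights[labs])
}

#' Observation mean of the glucose model
#'
#' `m(t) = r(t) + g(t)`: meal responses plus circadian baseline (or the
#' constant `A0` when `circadian = FALSE`).
#'
#' @param params a [glucose_params()].
#' @param meals a [meal_log()].
#' @param t time grid (hours).
#' @param circadian include the sinusoidal baseline?
#' @return numeric vector.
#' @export
model1_mean <- function(params, meals, t, circadian = TRUE) {
  cpp_model1_mean(glucose_par_vec(params), aligned_heights(params, meals),
                  t, meals$times, meal_label_index(meals),
                  circadian = circadian)
}

#' Exact log-likelihood of the glucose model
#'
#' Kalman-filter likelihood of the (detrended) glucose series given meal
#' events and parameters. Missing observations contribute prediction-only
#' steps. `engine = "cpp"` uses the specialized scalar filter; `"generic"`
#' routes through [kalman_filter()] (used for cross-validation).
#'
#' @param params a [glucose_params()].
#' @param record a [participant_record()] with a glucose series.
#' @param circadian include the circadian baseline?
#' @param engine `"cpp"` or `"generic"`.
#' @return log-likelihood (scalar).
#' @export
model1_loglik <- function(params, record, circadian = TRUE,
                          engine = c("cpp", "generic")) {
  engine <- match.arg(engine)
  g <- record$series$glucose
  if (is.null(g)) stop("record has no glucose series")
  meals <- record$meals
  if (engine == "cpp") {
    u <- glucose_pack(params, meals, circadian)
    return(cpp_model1_loglik_u(u$u, u$L, g$times, ifelse(g$missing, 0,
                                                         g$values),
                               as.integer(!g$missing), meals$times,
                               meal_label_index(meals), circadian))
  }
  sys <- glucose_system(params)
  m <- model1_mean(params, meals, g$times, circadian)
  y <- ifelse(g$missing, NA_real_, g$values)
  kalman_filter(sys, g$times, matrix(y - m, ncol = 1),
                H = matrix(c(0, 1), 1, 2), R = params$sigma^2)$loglik
}

# pack natural params to the unconstrained vector used by the C++ engine
glucose_pack <- function(params, meals, circadian = TRUE) {
  h <- aligned_heights(params, meals)
  L <- length(h)
  core <- log(c(params$A11, params$A12, params$A21, params$A22,
                max(params$B22, 1e-12), params$sigma))
  u <- if (circadian)
    c(core, params$A0, log(max(params$A1, 1e-12)), params$phi)
  else c(core, params$A0)
  list(u = c(u, log(pmax(h, 1e-12))), L = L)
}

# inverse of glucose_pack: unconstrained vector -> glucose_params
glucose_unpack <- function(u, labels, circadian = TRUE) {
  L <- length(labels)
  p <- exp(u[1:6])
  if (circadian) {
    off <- 9
    gp <- glucose_params(p[1], p[2], p[3], p[4], p[5],
                         A0 = u[7], A1 = exp(u[8]), phi = u[9] %% 24,
                         sigma = p[6])
  } else {
    off <- 7
    gp <- glucose_params(p[1], p[2], p[3], p[4], p[5],
                         A0 = u[7], A1 = 0, phi = 0, sigma = p[6])
  }
  if (L) gp$heights <- setNames(exp(u[off + seq_len(L)]), labels)
  gp
}

#' Summary metrics of a fitted glucose model
#'
#' Half-life, damping coefficient, mean meal height (averaged over meal
#' events, each occurrence counted), circadian amplitude and peak time.
#'
#' @param params a [glucose_params()].
#' @param meals a [meal_log()] used to weight meal heights by occurrence.
#' @return named list of scalars.
#' @export
glucose_metrics <- function(params, meals = meal_log()) {
  mh <- if (length(meals))
    mean(unname(params$heights[meals$labels])) else NA_real_
  list(half_life = half_life(params),
       damping = damping_coefficient(glucose_W(params)),
       mean_meal_height = mh,
       circadian_amplitude = params$A1,
       circadian_peak_time = params$phi %% 24)
}
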