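#' Default generating glucose parameters
#'
#' Mid-range truth used by the synthetic scenarios: an underdamped system
#' (damping coefficient -0.5) with the rates scaled to a response half-life
#' of 1.5 h, meal heights of order 1 mmol/L, a 0.8 mmol/L circadian
#' amplitude peaking mid-afternoon, and device-scale observation noise.
#'
#' @param heights named meal heights (mmol/L).
#' @return a [glucose_params()].
#' @export
true_glucose_params <- function(heights = c(breakfast = 1.0, lunch = 1.2,
                                            dinner = 0.8)) {
  # a = A11 = A22, b = A12 = A21 = a/sqrt(2) gives damping -0.5; the scale
  # factor sets half_life() = 1.5 h (computed once from the unit-rate system)
  a <- 0.826221  # = (unit-rate half-life 1.239331 h) / 1.5 h
  glucose_params(A11 = a, A12 = a / sqrt(2), A21 = a / sqrt(2), A22 = a,
                 B22 = 0.15, heights = heights, A0 = 4.2, A1 = 0.8,
                 phi = 15, sigma = 0.25)
}

#' Default generating activity/HR/HRV parameters
#'
#' Fast-relaxing activity (half-hour timescale) driving HR and HRV, with
#' moderately correlated HR-HRV fluctuations and circadian baselines in
#' normalized units.
#'
#' @return a [cardio_params()].
#' @export
true_cardio_params <- function() {
  cardio_params(C11 = 2, C21 = 3, C22 = 4, C31 = 2, C33 = 4,
                D11 = 2, D22 = 1.5, D33 = 1.5, rho = 0.5,
                circ = list(act = c(-0.3, 0.6, 14), hr = c(-0.4, 0.8, 16),
                            hrv = c(-0.2, 0.5, 4)),
                sigma = c(0.3, 0.2, 0.3))
}

#' Synthetic-participant scenario
#'
#' Describes one simulated participant: recording length and grids, meal
#' schedule (3-5 events/day at jittered conventional times with a recurring
#' label vocabulary so per-label heights are identifiable), the generating
#' model parameters, exercise bouts, and device missingness (random gaps).
#'
#' @param seed mandatory RNG seed.
#' @param model `"glucose"` (CGM + meals only) or `"combined"` (all four
#'   channels from the coupled 5-D model).
#' @param duration_days recording length (default 14).
#' @param cgm_step_min CGM sampling step (default 15 min).
#' @param aux_step_min activity/HR/HRV step (default 5 min; must divide
#'   `cgm_step_min`).
#' @param meals_per_day range of daily meal counts.
#' @param meal_jitter_h SD of meal-time jitter around conventional slots.
#' @param glucose a [glucose_params()] truth.
#' @param cardio a [cardio_params()] truth (combined model).
#' @param C5 true couplings (combined model).
#' @param gap_rate_per_day expected device gaps per day per channel.
#' @param gap_mean_h mean gap length (hours).
#' @param bout_rate_per_day expected exercise bouts per day.
#' @param bout_len_h,bout_height bout duration (h) and input height
#'   (normalized activity units).
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(seed, model = c("glucose", "combined"),
                          duration_days = 14, cgm_step_min = 15,
                          aux_step_min = 5, meals_per_day = c(3, 5),
                          meal_jitter_h = 0.75,
                          glucose = true_glucose_params(),
                          cardio = true_cardio_params(),
                          C5 = c(-0.5, 0.4, 0),
                          gap_rate_per_day = 0.5, gap_mean_h = 1.5,
                          bout_rate_per_day = 0.5, bout_len_h = 0.75,
                          bout_height = 2) {
  if (missing(seed) || is.null(seed)) stop("scenario seed is mandatory")
  model <- match.arg(model)
  if (cgm_step_min %% aux_step_min != 0)
    stop("aux_step_min must divide cgm_step_min")
  if ((24 * 60) %% cgm_step_min != 0)
    stop("cgm_step_min must divide the day")
  structure(list(seed = as.integer(seed), model = model,
                 duration_days = duration_days,
                 cgm_step_min = cgm_step_min, aux_step_min = aux_step_min,
                 meals_per_day = meals_per_day,
                 meal_jitter_h = meal_jitter_h, glucose = glucose,
                 cardio = cardio, C5 = C5,
                 gap_rate_per_day = gap_rate_per_day,
                 gap_mean_h = gap_mean_h,
                 bout_rate_per_day = bout_rate_per_day,
                 bout_len_h = bout_len_h, bout_height = bout_height),
            class = "scenario_spec")
}

# jittered conventional meal schedule with a recurring label vocabulary
simulate_meals <- function(spec) {
  slots <- c(breakfast = 7.5, lunch = 12.5, dinner = 19.5, snack = 16,
             coffee = 9.5)
  labs <- names(spec$glucose$heights)
  slots <- slots[names(slots) %in% labs]
  if (!length(slots))
    slots <- setNames(seq(8, 20, length.out = length(labs)), labs)
  core <- head(names(slots), min(3, length(slots)))
  times <- numeric(0); labels <- character(0)
  for (day in seq_len(spec$duration_days) - 1) {
    k <- sample(seq(spec$meals_per_day[1], spec$meals_per_day[2]), 1)
    pick <- core
    extra <- setdiff(names(slots), core)
    if (k > length(core) && length(extra))
      pick <- c(pick, sample(extra, min(k - length(core), length(extra))))
    tt <- 24 * day + slots[pick] + rnorm(length(pick), 0, spec$meal_jitter_h)
    tt <- pmin(pmax(tt, 24 * day + 0.5), 24 * day + 23.5)
    times <- c(times, tt)
    labels <- c(labels, pick)
  }
  meal_log(times, labels)
}

# random device gaps -> logical missing mask over a time grid
simulate_gaps <- function(times, spec) {
  miss <- rep(FALSE, length(times))
  span <- diff(range(times))
  n_gaps <- rpois(1, spec$gap_rate_per_day * span / 24)
  if (n_gaps > 0) {
    starts <- runif(n_gaps, min(times), max(times))
    lens <- stats::rexp(n_gaps, 1 / spec$gap_mean_h)
    for (i in seq_len(n_gaps))
      miss <- miss | (times >= starts[i] & times <= starts[i] + lens[i])
  }
  miss
}

mask_series <- function(s, miss) {
  s$values[miss] <- NA_real_
  s$missing <- miss
  s
}

# affine maps from normalized model units to device units
device_maps <- function() {
  list(activity = c(scale = 300, offset = 2000),
       hr = c(scale = 10, offset = 70),
       hrv = c(scale = 0.004, offset = 0.025))  # ms^-1
}

#' Generate a synthetic participant
#'
#' Simulates latent paths with the exact discrete-time recursion, adds the
#' meal/circadian observation means and device noise, applies random device
#' gaps, and returns both a device-unit record (as read from CSVs) and a
#' normalized record ready for fitting, plus the full truth bundle.
#' Exercise bouts enter the activity state as a square-wave input and
#' propagate through the couplings.
#'
#' @param spec a [scenario_spec()].
#' @return list with `record` (device units), `record_normalized`
#'   (model units) and `truth` (spec, parameters, latent states, maps).
#' @export
generate_participant <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  D <- spec$duration_days
  t_cgm <- seq(spec$cgm_step_min / 60, D * 24, by = spec$cgm_step_min / 60)
  meals <- simulate_meals(spec)
  gp <- spec$glucose

  if (spec$model == "glucose") {
    sys <- glucose_system(gp)
    m <- model1_mean(gp, meals, t_cgm)
    sim <- simulate_path(sys, t_cgm, H = matrix(c(0, 1), 1, 2),
                         m = matrix(m, ncol = 1), R = gp$sigma^2)
    gl <- sensor_series("glucose", t_cgm, pmax(drop(sim$y), 0.1))
    gl <- mask_series(gl, simulate_gaps(t_cgm, spec))
    rec <- participant_record("SYN", list(glucose = gl), meals,
                              window = c(0, D * 24))
    return(list(record = rec, record_normalized = rec,
                truth = list(spec = spec, glucose = gp, meals = meals,
                             states = sim$states, times = t_cgm)))
  }

  cp <- combined_params(spec$cardio, gp, spec$C5)
  sys <- build_combined_system(cp)
  t_aux <- seq(spec$aux_step_min / 60, D * 24, by = spec$aux_step_min / 60)
  # stochastic latent part
  sim <- simulate_path(sys, t_aux, H = diag(5), m = NULL,
                       R = diag(0, 5))
  X <- sim$states
  # deterministic exercise-bout component through the full coupled system
  n_bouts <- rpois(1, spec$bout_rate_per_day * D)
  u <- rep(0, length(t_aux))
  if (n_bouts > 0) {
    starts <- runif(n_bouts, 0, D * 24 - spec$bout_len_h)
    for (s in starts)
      u[t_aux >= s & t_aux <= s + spec$bout_len_h] <- spec$bout_height
  }
  if (any(u != 0)) {
    W <- combined_W(cp)
    tr <- discretize(sys, spec$aux_step_min / 60)
    Bu <- solve(W, (tr$F - diag(5))[, 1])  # W^-1 (F - I) e1
    xdet <- matrix(0, length(t_aux), 5)
    for (k in 2:length(t_aux))
      xdet[k, ] <- drop(tr$F %*% xdet[k - 1, ]) + Bu * u[k - 1]
    X <- X + xdet
  }
  # observations
  g_aux <- cardio_mean(cp$cardio, t_aux)
  y_aux <- X[, 1:3] + g_aux +
    matrix(rnorm(3 * length(t_aux)), ncol = 3) %*%
    diag(cp$cardio$sigma)
  idx <- match(round(t_cgm, 9), round(t_aux, 9))
  m_gluc <- model1_mean(gp, meals, t_cgm)
  y_gluc <- X[idx, 5] + m_gluc + rnorm(length(t_cgm), 0, gp$sigma)

  maps <- device_maps()
  mk <- function(ch, vals, times) {
    s <- sensor_series(ch, times, vals)
    mask_series(s, simulate_gaps(times, spec))
  }
  norm_rec <- participant_record(
    "SYN",
    list(glucose = mk("glucose", pmax(y_gluc, 0.1), t_cgm),
         activity = mk("activity", y_aux[, 1], t_aux),
         hr = mk("hr", y_aux[, 2], t_aux),
         hrv = mk("hrv", y_aux[, 3], t_aux)),
    meals, window = c(0, D * 24))
  dev <- function(ch, s) {
    mp <- maps[[ch]]
    s$values <- s$values * mp[["scale"]] + mp[["offset"]]
    s
  }
  dev_rec <- norm_rec
  for (ch in cardio_channels)
    dev_rec$series[[ch]] <- dev(ch, norm_rec$series[[ch]])
  list(record = dev_rec, record_normalized = norm_rec,
       truth = list(spec = spec, combined = cp, meals = meals,
                    states = X, times = t_aux, maps = maps, bouts = u))
}

#' Parameter-recovery study for the glucose model
#'
#' Simulates `n_replicates` participants from a scenario, fits each with
#' MAP + HMC, and reports per-parameter bias, RMSE and credible-interval
#' coverage, plus recovery of the derived metrics (half-life, damping
#' sign, circadian amplitude and peak time). Non-finite fits are flagged
#' and excluded with a count.
#'
#' @param spec a [scenario_spec()] with `model = "glucose"`.
#' @param n_replicates number of simulated participants (>= 5).
#' @param config an [hmc_config()] (use reduced counts for test scale).
#' @param level credible level for coverage (default 0.9).
#' @return list with `parameters` (data.frame), `metrics` (data.frame),
#'   `n_failed`.
#' @export
recovery_study <- function(spec, n_replicates, config = hmc_config(),
                           level = 0.9) {
  stopifnot(n_replicates >= 5, spec$model == "glucose")
  a <- (1 - level) / 2
  res <- list()
  met <- list()
  n_failed <- 0
  for (i in seq_len(n_replicates)) {
    sp <- spec
    sp$seed <- spec$seed + i
    gen <- generate_participant(sp)
    fit <- tryCatch(
      fit_model1(gen$record, circadian = TRUE, config = config,
                 ev_draws = 0),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$samples$draws))) {
      n_failed <- n_failed + 1
      next
    }
    truth <- truth_param_vec(spec$glucose, fit$labels)
    nd <- fit$natural_draws
    lo <- apply(nd, 2, quantile, a)
    hi <- apply(nd, 2, quantile, 1 - a)
    est <- apply(nd, 2, stats::median)
    res[[length(res) + 1]] <- data.frame(
      parameter = colnames(nd), truth = truth, estimate = est,
      covered = truth >= lo & truth <= hi, replicate = i)
    tm <- glucose_metrics(spec$glucose, gen$truth$meals)
    md <- fit$metric_draws
    met[[length(met) + 1]] <- data.frame(
      replicate = i,
      half_life_med = stats::median(md[, "half_life"], na.rm = TRUE),
      half_life_true = tm$half_life,
      damping_sign_ok = sign(stats::median(md[, "damping"])) ==
        sign(tm$damping),
      amplitude_med = stats::median(md[, "circadian_amplitude"]),
      amplitude_true = tm$circadian_amplitude,
      peak_err_h = circ_diff(stats::median(md[, "circadian_peak_time"]),
                             tm$circadian_peak_time))
  }
  if (!length(res)) stop("all replicates failed")
  allp <- do.call(rbind, res)
  par_tab <- do.call(rbind, lapply(split(allp, allp$parameter), function(d)
    data.frame(parameter = d$parameter[1],
               bias = mean(d$estimate - d$truth),
               rmse = sqrt(mean((d$estimate - d$truth)^2)),
               coverage = mean(d$covered),
               n = nrow(d))))
  list(parameters = par_tab, metrics = do.call(rbind, met),
       n_failed = n_failed)
}

# truth vector aligned with fitted parameter names (circadian model)
truth_param_vec <- function(gp, labels) {
  c(gp$A11, gp$A12, gp$A21, gp$A22, gp$B22, gp$sigma, gp$A0, gp$A1,
    gp$phi, unname(gp$heights[labels]))
}

circ_diff <- function(a, b) {
  d <- (a - b) %% 24
  min(d, 24 - d)
}

#' Load a shipped scenario preset
#'
#' Presets are JSON files under `inst/extdata/presets/`: `"high-circadian"`
#' (glucose amplitude 1.5 mmol/L), `"underdamped"` (the default mid-range
#' glucose truth), `"exercise-spiker"` (combined model with frequent bouts
#' and strong couplings) and `"null-coupling"` (combined model, all C5 = 0).
#'
#' @param name preset name.
#' @param seed RNG seed for the resulting [scenario_spec()].
#' @return a [scenario_spec()].
#' @export
scenario_preset <- function(name, seed) {
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "wearssm")
  if (path == "") stop("unknown preset: ", name)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  gp <- true_glucose_params()
  for (nm in names(js$glucose)) {
    if (nm == "heights") gp$heights <- unlist(js$glucose$heights)
    else gp[[nm]] <- js$glucose[[nm]]
  }
  args <- list(seed = seed, model = js$model %||% "glucose", glucose = gp)
  if (!is.null(js$C5)) args$C5 <- as.numeric(js$C5)
  for (nm in c("duration_days", "cgm_step_min", "aux_step_min",
               "gap_rate_per_day", "gap_mean_h", "bout_rate_per_day",
               "bout_len_h", "bout_height"))
    if (!is.null(js[[nm]])) args[[nm]] <- js[[nm]]
  do.call(scenario_spec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
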