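#' Sensor time series
#'
#' A single wearable channel: strictly increasing timestamps (hours since
#' local midnight of study day 1), values in channel units, and a missingness
#' mask. Glucose is in mmol/L, activity in counts/epoch, HR in bpm, HRV in
#' ms^-1 after inversion of RMSSD.
#'
#' @param channel one of `"glucose"`, `"activity"`, `"hr"`, `"hrv"`.
#' @param times numeric, strictly increasing, hours since local midnight of
#'   study day 1 (so wall-clock time of day is `times %% 24`).
#' @param values numeric, same length as `times`; entries at missing
#'   timestamps may be `NA`.
#' @param missing logical mask aligned with `times`; defaults to `is.na(values)`.
#' @param unit unit string (informational).
#' @return an object of class `sensor_series`.
#' @export
sensor_series <- function(channel, times, values, missing = is.na(values),
                          unit = NULL) {
  channel <- match.arg(channel, c("glucose", "activity", "hr", "hrv"))
  times <- as.numeric(times)
  values <- as.numeric(values)
  missing <- as.logical(missing)
  if (length(values) != length(times) || length(missing) != length(times))
    stop("times, values and missing must have equal length")
  if (anyNA(times)) stop("timestamps must be finite")
  if (is.unsorted(times, strictly = TRUE)) {
    d <- which(diff(times) <= 0)[1]
    stop(sprintf("timestamps must be strictly increasing; violation at t = %.6f h",
                 times[d + 1]))
  }
  if (any(!missing & !is.finite(values)))
    stop("non-finite value at an observed (missing = FALSE) timestamp")
  if (channel == "glucose" && any(!missing & values <= 0))
    stop("observed glucose values must be positive (mmol/L)")
  if (is.null(unit))
    unit <- c(glucose = "mmol/L", activity = "counts", hr = "bpm",
              hrv = "1/ms")[[channel]]
  structure(list(channel = channel, times = times, values = values,
                 missing = missing, unit = unit),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series: %s [%s], %d points over %.1f h, %.1f%% missing>\n",
              x$channel, x$unit, length(x$times),
              diff(range(x$times)), 100 * mean(x$missing)))
  invisible(x)
}

#' Observed (non-missing) part of a sensor series
#' @param x a [sensor_series()].
#' @return list with `times` and `values` at observed points.
#' @export
observed <- function(x) {
  stopifnot(inherits(x, "sensor_series"))
  list(times = x$times[!x$missing], values = x$values[!x$missing])
}

#' Meal log
#'
#' Timestamped ingestion events with free-text annotations. Annotations are
#' normalized (lowercase, collapsed whitespace) by default; events with the
#' same normalized label share one meal-height parameter when fitting.
#'
#' @param times numeric, hours since local midnight of study day 1.
#' @param labels character annotations, same length as `times`.
#' @param normalize normalize labels (lowercase + whitespace collapse)?
#' @return object of class `meal_log`, sorted by time.
#' @export
meal_log <- function(times = numeric(), labels = character(),
                     normalize = TRUE) {
  times <- as.numeric(times)
  labels <- as.character(labels)
  if (length(labels) != length(times))
    stop("times and labels must have equal length")
  if (anyNA(times)) stop("meal times must be finite")
  if (normalize) labels <- normalize_label(labels)
  o <- order(times)
  structure(list(times = times[o], labels = labels[o]), class = "meal_log")
}

normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' @export
print.meal_log <- function(x, ...) {
  cat(sprintf("<meal_log: %d events, %d unique labels>\n",
              length(x$times), length(unique(x$labels))))
  invisible(x)
}

#' @export
length.meal_log <- function(x) length(x$times)

#' Participant record
#'
#' Bundles all channels and the meal log for one participant, with the
#' recording window in hours since local midnight of study day 1.
#'
#' @param participant_id identifier string.
#' @param series named list of [sensor_series()] (names are channels).
#' @param meals a [meal_log()].
#' @param window length-2 numeric `(start, end)` in hours; defaults to the
#'   span of the data.
#' @return object of class `participant_record`.
#' @export
participant_record <- function(participant_id, series, meals = meal_log(),
                               window = NULL) {
  stopifnot(is.list(series), inherits(meals, "meal_log"))
  for (s in series) stopifnot(inherits(s, "sensor_series"))
  names(series) <- vapply(series, `[[`, "", "channel")
  rng <- range(unlist(lapply(series, `[[`, "times")))
  if (is.null(window)) window <- c(floor(rng[1]), ceiling(rng[2]))
  if (rng[1] < window[1] || rng[2] > window[2])
    stop("sensor timestamps fall outside the recording window")
  if (length(meals) &&
      (min(meals$times) < window[1] || max(meals$times) > window[2]))
    stop("meal events fall outside the recording window")
  structure(list(participant_id = participant_id, series = series,
                 meals = meals, window = window),
            class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record %s: %s; %d meals; window [%.0f, %.0f] h>\n",
              x$participant_id, paste(names(x$series), collapse = ", "),
              length(x$meals), x$window[1], x$window[2]))
  invisible(x)
}

#' Meal-logging adherence
#'
#' Fraction of study days with at least two logged meals separated by at
#' least 5 hours. Days are delimited by local midnight; a day's largest
#' pairwise gap between meal times must reach 5 h for the day to qualify.
#'
#' @param meals a [meal_log()].
#' @param days number of study days (>= 1).
#' @param min_gap qualifying separation in hours (default 5).
#' @return fraction in `[0, 1]`.
#' @export
adherence <- function(meals, days, min_gap = 5) {
  stopifnot(inherits(meals, "meal_log"), days >= 1)
  if (!length(meals)) return(0)
  day <- floor(meals$times / 24)
  ok <- vapply(split(meals$times, day), function(tt) {
    length(tt) >= 2 && (max(tt) - min(tt)) >= min_gap
  }, logical(1))
  sum(ok) / days
}

#' Unique meal labels with event counts
#'
#' Labels in order of first occurrence; counts sum to the number of events.
#'
#' @param meals a [meal_log()].
#' @return named integer vector of counts.
#' @export
unique_meal_labels <- function(meals) {
  stopifnot(inherits(meals, "meal_log"))
  if (!length(meals)) return(setNames(integer(), character()))
  lev <- unique(meals$labels)
  tab <- table(factor(meals$labels, levels = lev))
  setNames(as.integer(tab), lev)
}

#' 1-based label index per meal event
#' @param meals a [meal_log()].
#' @return integer vector aligned with `meals$times`.
#' @keywords internal
meal_label_index <- function(meals) {
  lev <- names(unique_meal_labels(meals))
  match(meals$labels, lev)
}
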