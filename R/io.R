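#' Default CSV dialect for device exports
#'
#' Column mapping and timestamp handling for the three input files: a CGM
#' export (timestamp, glucose in mmol/L), an Actiheart-style export
#' (timestamp, activity counts, HR in bpm, RMSSD in ms) and a meal log
#' (timestamp, free-text annotation). Timestamps are ISO
#' `"YYYY-MM-DD HH:MM:SS"`; `start_date` anchors hour 0 at local midnight of
#' study day 1.
#'
#' @param start_date ISO date of study day 1.
#' @param cgm,actiheart,meal named character vectors mapping roles to column
#'   names.
#' @param normalize_labels normalize meal annotations?
#' @return a list used by [read_participant()] / [write_participant()].
#' @export
csv_dialect <- function(start_date = "2023-01-02",
                        cgm = c(timestamp = "timestamp",
                                glucose = "glucose_mmol_L"),
                        actiheart = c(timestamp = "timestamp",
                                      activity = "activity_counts",
                                      hr = "hr_bpm", hrv = "rmssd_ms"),
                        meal = c(timestamp = "timestamp",
                                 annotation = "annotation"),
                        normalize_labels = TRUE) {
  list(start_date = start_date, cgm = cgm, actiheart = actiheart,
       meal = meal, normalize_labels = normalize_labels)
}

iso_to_hours <- function(x, start_date) {
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  tt <- as.POSIXct(x, tz = "UTC")
  if (anyNA(tt)) stop("unparseable timestamp: ", x[which(is.na(tt))[1]])
  as.numeric(difftime(tt, t0, units = "hours"))
}

hours_to_iso <- function(h, start_date) {
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  format(t0 + round(h * 3600), "%Y-%m-%d %H:%M:%S")
}

check_dupes <- function(h, what, raw) {
  d <- which(duplicated(h))
  if (length(d))
    stop(sprintf("duplicated timestamp in %s file: %s", what, raw[d[1]]))
}

#' Read one participant's device CSV files
#'
#' @param cgm_file,actiheart_file,meal_file paths to the three CSVs; any may
#'   be `NULL` (the channel is then absent; a missing meal file yields an
#'   empty log).
#' @param dialect a [csv_dialect()].
#' @param participant_id identifier.
#' @param window optional recording window in hours; rows outside it are
#'   dropped with a message.
#' @return a [participant_record()].
#' @export
read_participant <- function(cgm_file = NULL, actiheart_file = NULL,
                             meal_file = NULL, dialect = csv_dialect(),
                             participant_id = "P01", window = NULL) {
  series <- list()
  clip <- function(h, keep_src) {
    if (is.null(window)) return(rep(TRUE, length(h)))
    ok <- h >= window[1] & h <= window[2]
    if (any(!ok)) message(sum(!ok), " out-of-window rows dropped from ",
                          keep_src)
    ok
  }
  need_cols <- function(df, map, what) {
    miss <- setdiff(unname(map), names(df))
    if (length(miss))
      stop(sprintf("%s file is missing mandatory column(s): %s", what,
                   paste(miss, collapse = ", ")))
  }
  if (!is.null(cgm_file)) {
    df <- read.csv(cgm_file, stringsAsFactors = FALSE)
    need_cols(df, dialect$cgm, "CGM")
    h <- iso_to_hours(df[[dialect$cgm[["timestamp"]]]], dialect$start_date)
    check_dupes(h, "CGM", df[[dialect$cgm[["timestamp"]]]])
    o <- order(h); df <- df[o, , drop = FALSE]; h <- h[o]
    ok <- clip(h, "CGM")
    series$glucose <- sensor_series("glucose", h[ok],
                                    df[[dialect$cgm[["glucose"]]]][ok])
  }
  if (!is.null(actiheart_file)) {
    df <- read.csv(actiheart_file, stringsAsFactors = FALSE)
    need_cols(df, dialect$actiheart, "Actiheart")
    h <- iso_to_hours(df[[dialect$actiheart[["timestamp"]]]],
                      dialect$start_date)
    check_dupes(h, "Actiheart", df[[dialect$actiheart[["timestamp"]]]])
    o <- order(h); df <- df[o, , drop = FALSE]; h <- h[o]
    ok <- clip(h, "Actiheart")
    series$activity <- sensor_series("activity", h[ok],
                                     df[[dialect$actiheart[["activity"]]]][ok])
    series$hr <- sensor_series("hr", h[ok],
                               df[[dialect$actiheart[["hr"]]]][ok])
    rmssd <- sensor_series("hrv", h[ok],
                           df[[dialect$actiheart[["hrv"]]]][ok], unit = "ms")
    series$hrv <- rmssd_inverse(rmssd)
  }
  meals <- meal_log()
  if (!is.null(meal_file)) {
    df <- read.csv(meal_file, stringsAsFactors = FALSE)
    need_cols(df, dialect$meal, "meal")
    if (nrow(df)) {
      h <- iso_to_hours(df[[dialect$meal[["timestamp"]]]], dialect$start_date)
      ok <- clip(h, "meal log")
      meals <- meal_log(h[ok], df[[dialect$meal[["annotation"]]]][ok],
                        normalize = dialect$normalize_labels)
    }
  }
  if (!length(series)) stop("no sensor file supplied")
  participant_record(participant_id, series, meals, window = window)
}

#' Write a participant record as device-format CSV files
#'
#' Inverse of [read_participant()]: writes `cgm.csv`, `actiheart.csv` and
#' `meals.csv` into `dir`. The HRV channel (ms^-1) is converted back to
#' RMSSD in ms. Timestamps are rounded to the second.
#'
#' @param record a [participant_record()].
#' @param dir output directory (created if needed).
#' @param dialect a [csv_dialect()].
#' @return `dir`, invisibly.
#' @export
write_participant <- function(record, dir, dialect = csv_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sd <- dialect$start_date
  g <- record$series$glucose
  if (!is.null(g)) {
    df <- data.frame(hours_to_iso(g$times, sd), g$values)
    names(df) <- dialect$cgm[c("timestamp", "glucose")]
    write.csv(df, file.path(dir, "cgm.csv"), row.names = FALSE, quote = FALSE)
  }
  a <- record$series$activity
  if (!is.null(a)) {
    rmssd <- 1 / record$series$hrv$values
    df <- data.frame(hours_to_iso(a$times, sd), a$values,
                     record$series$hr$values, rmssd)
    names(df) <- dialect$actiheart[c("timestamp", "activity", "hr", "hrv")]
    write.csv(df, file.path(dir, "actiheart.csv"), row.names = FALSE,
              quote = FALSE)
  }
  df <- data.frame(hours_to_iso(record$meals$times, sd),
                   record$meals$labels)
  names(df) <- dialect$meal[c("timestamp", "annotation")]
  write.csv(df, file.path(dir, "meals.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' JSON summary of a participant record
#'
#' Counts, per-channel coverage and meal-logging adherence, written as JSON.
#'
#' @param record a [participant_record()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
participant_summary <- function(record, path = NULL) {
  days <- ceiling(diff(record$window) / 24)
  cov <- lapply(record$series, function(s) {
    list(n = length(s$times), observed = sum(!s$missing),
         coverage = round(mean(!s$missing), 4), unit = s$unit)
  })
  out <- list(participant_id = record$participant_id,
              window_hours = record$window,
              days = days,
              channels = cov,
              n_meals = length(record$meals),
              n_meal_labels = length(unique(record$meals$labels)),
              adherence = adherence(record$meals, days))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
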