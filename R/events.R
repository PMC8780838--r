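#' Event log of one participant
#'
#' A chronologically ordered sequence of PIR motion-sensor firings for one
#' participant. The raw observable of the whole analysis: every downstream
#' quantity (daily graphs, baselines, percent differences, trends) is a
#' function of these timestamps and sensor ids.
#'
#' @param participant_id Scalar identifier.
#' @param events data.frame with columns `timestamp` (POSIXct) and
#'   `sensor_id` (character).
#' @param sort Sort events by timestamp (default `TRUE`). With `sort = FALSE`
#'   out-of-order input is an error.
#' @return An object of class `event_log`: list with `participant_id` and
#'   `events`.
#' @export
event_log <- function(participant_id, events, sort = TRUE) {
  stopifnot(is.data.frame(events),
            all(c("timestamp", "sensor_id") %in% names(events)))
  events <- events[, c("timestamp", "sensor_id")]
  if (!inherits(events$timestamp, "POSIXct"))
    stop("timestamp must be POSIXct")
  events$sensor_id <- as.character(events$sensor_id)
  if (sort) {
    events <- events[order(events$timestamp), , drop = FALSE]
  } else if (is.unsorted(as.numeric(events$timestamp))) {
    stop("events are not sorted by timestamp and sort = FALSE")
  }
  rownames(events) <- NULL
  structure(list(participant_id = as.character(participant_id)[1L],
                 events = events),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> participant ", x$participant_id, ": ",
      nrow(x$events), " events", sep = "")
  if (nrow(x$events))
    cat(" (", format(min(x$events$timestamp)), " .. ",
        format(max(x$events$timestamp)), ")", sep = "")
  cat("\n")
  invisible(x)
}

parse_timestamps <- function(x, tz, context = "timestamp") {
  fmts <- c("%Y-%m-%dT%H:%M:%OS%z", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS%z", "%Y-%m-%d %H:%M:%OS")
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (fmt in fmts) {
    need <- is.na(ts)
    if (!any(need)) break
    ts[need] <- as.POSIXct(x[need], tz = tz, format = fmt, optional = TRUE)
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop("malformed ", context, " in row ", bad, ": '", x[bad], "'")
  }
  ts
}

#' Read an event log from CSV
#'
#' The file must have the header `timestamp,participant_id,sensor_id`, one
#' event per row, ISO 8601 timestamps (with or without a UTC offset;
#' offset-less timestamps are interpreted in `tz`).
#'
#' @param path CSV file path.
#' @param tz Time zone applied to offset-less timestamps. Default `"UTC"`.
#' @param sort Sort rows by timestamp after reading (default `TRUE`).
#' @return An [event_log()].
#' @export
read_event_log <- function(path, tz = "UTC", sort = TRUE) {
  if (!file.exists(path)) stop("event log file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("timestamp", "participant_id", "sensor_id")
  if (!all(need %in% names(df)))
    stop("event log must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) {
    return(event_log("unknown",
                     data.frame(timestamp = as.POSIXct(character(), tz = tz),
                                sensor_id = character())))
  }
  pid <- unique(df$participant_id)
  if (length(pid) != 1L)
    stop("event log mixes participant ids: ", paste(pid, collapse = ", "))
  ts <- parse_timestamps(df$timestamp, tz)
  event_log(pid, data.frame(timestamp = ts, sensor_id = df$sensor_id),
            sort = sort)
}

#' Write an event log to CSV
#'
#' @param log An [event_log()].
#' @param path Output path.
#' @param tz Time zone used to format timestamps. Default `"UTC"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, tz = "UTC") {
  stopifnot(inherits(log, "event_log"))
  df <- data.frame(
    timestamp = format(log$events$timestamp, "%Y-%m-%dT%H:%M:%S%z", tz = tz),
    participant_id = log$participant_id,
    sensor_id = log$events$sensor_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an event log against a topology and the sensor cool-down
#'
#' PIR sensors cannot re-fire within their 8 s cool-down, so two events from
#' the same sensor less than 8 s apart indicate clock trouble, duplicated
#' rows, or a second person. Validation counts violations; it never mutates
#' or drops events (use [drop_cooldown_violations()] for cleaning).
#'
#' @param log An [event_log()].
#' @param topology A [flat_topology()] (for unknown-sensor detection), or
#'   `NULL` to skip that check.
#' @param cooldown Minimum legal same-sensor spacing in seconds; a gap of
#'   exactly `cooldown` is legal. Default 8.
#' @return A list of class `validation_report` with counts
#'   (`n_unknown_sensor`, `n_out_of_order`, `n_cooldown_violation`) and the
#'   offending row indices.
#' @export
validate_event_log <- function(log, topology = NULL, cooldown = 8) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  t <- as.numeric(ev$timestamp)
  ooo <- if (length(t) > 1L) which(diff(t) < 0) + 1L else integer()
  unknown <- integer()
  if (!is.null(topology)) {
    known <- names(topology$sensors)
    unknown <- which(!(ev$sensor_id %in% known))
  }
  cool <- integer()
  if (nrow(ev) > 1L) {
    o <- order(ev$sensor_id, t)
    ts <- t[o]
    same <- ev$sensor_id[o][-1L] == ev$sensor_id[o][-length(o)]
    viol <- same & (diff(ts) < cooldown)
    cool <- sort(o[-1L][viol])
  }
  structure(list(n_unknown_sensor = length(unknown),
                 n_out_of_order = length(ooo),
                 n_cooldown_violation = length(cool),
                 unknown_sensor_rows = unknown,
                 out_of_order_rows = ooo,
                 cooldown_violation_rows = cool),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> unknown sensors: ", x$n_unknown_sensor,
      "; out of order: ", x$n_out_of_order,
      "; cool-down violations: ", x$n_cooldown_violation, "\n", sep = "")
  invisible(x)
}

#' Drop events violating the sensor cool-down
#'
#' Greedy front-to-back thinning: an event is kept only if it is at least
#' `cooldown` seconds after the previously kept event of the same sensor.
#'
#' @inheritParams validate_event_log
#' @return A cleaned [event_log()].
#' @export
drop_cooldown_violations <- function(log, cooldown = 8) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  if (nrow(ev) < 2L) return(log)
  keep <- rep(TRUE, nrow(ev))
  t <- as.numeric(ev$timestamp)
  for (s in unique(ev$sensor_id)) {
    idx <- which(ev$sensor_id == s)
    last <- -Inf
    for (i in idx) {
      if (t[i] - last < cooldown) keep[i] <- FALSE else last <- t[i]
    }
  }
  event_log(log$participant_id, ev[keep, , drop = FALSE], sort = FALSE)
}

#' Split an event log into civil days
#'
#' Each day is processed independently downstream: event pairs spanning
#' midnight do not form transitions, so a daily matrix is computable from a
#' day's events alone.
#'
#' @param log An [event_log()], sorted.
#' @param tz Time zone whose civil midnight defines day boundaries.
#' @return A named list (names are ISO dates) of `day_events` objects, one
#'   per calendar date with at least one event; days with no events are
#'   omitted. Each element has `participant_id`, `date` (a `Date`), and
#'   `events`.
#' @export
split_by_day <- function(log, tz = "UTC") {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events
  if (nrow(ev) == 0L) return(structure(list(), names = character()))
  dates <- as.Date(format(ev$timestamp, "%Y-%m-%d", tz = tz))
  parts <- split(seq_len(nrow(ev)), dates)
  out <- lapply(names(parts), function(d) {
    structure(list(participant_id = log$participant_id,
                   date = as.Date(d),
                   events = ev[parts[[d]], , drop = FALSE]),
              class = "day_events")
  })
  names(out) <- names(parts)
  out[order(as.Date(names(out)))]
}

#' Read geriatric assessment records from CSV
#'
#' Header `participant_id,date,sppb,tug` (optionally `frailty_index`).
#' SPPB is the Short Physical Performance Battery, 0-12 points, higher is
#' better; TUG is the Timed Up and Go time in seconds, lower is better.
#'
#' @param path CSV file path.
#' @return data.frame with typed columns, sorted by participant then date.
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) stop("assessments file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "sppb", "tug")
  if (!all(need %in% names(df)))
    stop("assessments must have columns: ", paste(need, collapse = ", "))
  df$participant_id <- as.character(df$participant_id)
  df$date <- as.Date(df$date)
  df$sppb <- as.numeric(df$sppb)
  df$tug <- as.numeric(df$tug)
  if (any(!is.na(df$sppb) & (df$sppb < 0 | df$sppb > 12)))
    stop("SPPB scores must be within 0..12 points")
  if (any(!is.na(df$tug) & df$tug <= 0))
    stop("TUG times must be positive seconds")
  df[order(df$participant_id, df$date), , drop = FALSE]
}
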