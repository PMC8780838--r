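#' Participant status record
#'
#' Metadata driving the participant- and day-level filters: group membership,
#' the three exclusion criteria (death during the study, change in living
#' situation, an incident compromising mobility), and declared absence
#' intervals (vacation, short-term care, hospitalization).
#'
#' @param participant_id Scalar identifier.
#' @param group `"intervention"` or `"control"`.
#' @param deceased,living_change,incident Onset `Date` of the respective
#'   exclusion criterion, or `NULL`/`NA` if it does not apply.
#' @param absences data.frame with columns `start`, `end` (Dates, inclusive)
#'   and `reason`; intervals must not overlap.
#' @return Object of class `participant_status`.
#' @export
participant_status <- function(participant_id,
                               group = c("intervention", "control"),
                               deceased = NULL, living_change = NULL,
                               incident = NULL, absences = NULL) {
  group <- match.arg(group)
  as_flag_date <- function(x) {
    if (is.null(x) || all(is.na(x))) return(as.Date(NA)) else as.Date(x)[1L]
  }
  if (is.null(absences)) {
    absences <- data.frame(start = as.Date(character()),
                           end = as.Date(character()),
                           reason = character())
  } else {
    absences <- data.frame(start = as.Date(absences$start),
                           end = as.Date(absences$end),
                           reason = as.character(absences$reason))
    if (any(absences$end < absences$start))
      stop("absence interval ends before it starts")
    absences <- absences[order(absences$start), , drop = FALSE]
    if (nrow(absences) > 1L &&
        any(absences$start[-1L] <= absences$end[-nrow(absences)]))
      stop("absence intervals overlap")
    rownames(absences) <- NULL
  }
  structure(list(participant_id = as.character(participant_id)[1L],
                 group = group,
                 deceased = as_flag_date(deceased),
                 living_change = as_flag_date(living_change),
                 incident = as_flag_date(incident),
                 absences = absences),
            class = "participant_status")
}

#' Apply the participant-level exclusion criteria
#'
#' A participant is excluded if any criterion applies: died during the
#' study, changed living situation (e.g. moved to a nursing home, flat
#' renovated), or suffered an incident compromising mobility (e.g. a severe
#' fall leading to wheelchair use).
#'
#' @param statuses List of [participant_status()] objects.
#' @return List with `included` (the retained statuses), `included_ids`,
#'   and `report`: a data.frame with one row per participant giving the
#'   verdict and the criterion that triggered exclusion.
#' @export
filter_participants <- function(statuses) {
  crits <- vapply(statuses, function(s) {
    if (!is.na(s$deceased)) "deceased"
    else if (!is.na(s$living_change)) "living-situation-change"
    else if (!is.na(s$incident)) "mobility-compromising-incident"
    else NA_character_
  }, character(1))
  ids <- vapply(statuses, `[[`, character(1), "participant_id")
  keep <- is.na(crits)
  list(included = statuses[keep],
       included_ids = ids[keep],
       report = data.frame(participant_id = ids,
                           excluded = !keep,
                           criterion = crits,
                           stringsAsFactors = FALSE))
}

#' Remove declared absence days from a difference series
#'
#' Days inside any declared absence interval (inclusive bounds) are dropped:
#' an empty or visitor-occupied flat says nothing about the resident's
#' mobility. Intervals are authoritative metadata; nothing outside them is
#' ever removed.
#'
#' @param series A `difference_series` from [daily_series()].
#' @param status A [participant_status()].
#' @return The filtered series; attribute `n_removed` holds the count of
#'   removed days.
#' @export
filter_absence_days <- function(series, status) {
  stopifnot(inherits(status, "participant_status"))
  ab <- status$absences
  absent <- rep(FALSE, nrow(series))
  for (k in seq_len(nrow(ab)))
    absent <- absent | (series$date >= ab$start[k] & series$date <= ab$end[k])
  at <- attributes(series)
  out <- series[!absent, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "participant_id") <- at$participant_id
  attr(out, "baseline_dates") <- at$baseline_dates
  class(out) <- c("difference_series", "data.frame")
  attr(out, "n_removed") <- sum(absent)
  out
}

#' Flag low-activity days as absence candidates
#'
#' Advisory aid for record keeping: a day whose event count (unmasked matrix
#' total + 1) falls below `threshold` is flagged for review. Flags never
#' remove days automatically; low counts alone cannot distinguish absence
#' from inactivity.
#'
#' @param dailies Named list (ISO dates) of unmasked daily
#'   [adjacency_matrix()] objects.
#' @param threshold Events per day below which a day is flagged (default 10).
#' @return Character vector of flagged dates.
#' @export
detect_absence_candidates <- function(dailies, threshold = 10) {
  counts <- vapply(dailies, function(A) sum(A) + 1, numeric(1))
  names(counts)[counts < threshold]
}

#' Cohort disposition bias check
#'
#' Compares each metric-scale cohort variable (age, frailty index, SPPB,
#' TUG, ...) between two groups with an unpaired two-sample rank test
#' (Mann-Whitney), to verify that filtering did not bias the analysed
#' sub-cohort.
#'
#' @param groupA,groupB data.frames with one row per participant and the
#'   same numeric columns.
#' @param alpha Significance level for the same/different verdict
#'   (default 0.01).
#' @param variables Variables to test; default all shared numeric columns.
#' @return data.frame with per-variable test statistic, p-value, and
#'   verdict (`"same"` / `"different"` at `alpha`).
#' @export
cohort_bias_check <- function(groupA, groupB, alpha = 0.01,
                              variables = NULL) {
  if (is.null(variables)) {
    shared <- intersect(names(groupA), names(groupB))
    variables <- shared[vapply(shared, function(v)
      is.numeric(groupA[[v]]) && is.numeric(groupB[[v]]), logical(1))]
  }
  if (!length(variables)) stop("no shared numeric variables to test")
  rows <- lapply(variables, function(v) {
    a <- groupA[[v]][!is.na(groupA[[v]])]
    b <- groupB[[v]][!is.na(groupB[[v]])]
    if (length(a) < 2L || length(b) < 2L)
      stop("insufficient data for variable '", v,
           "': need at least 2 values per group")
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(variable = v,
               statistic = unname(wt$statistic),
               p_value = wt$p.value,
               verdict = if (wt$p.value < alpha) "different" else "same",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Read / write participant statuses as JSON
#'
#' One JSON object per participant: group, exclusion flags with ISO dates,
#' absence intervals with reasons.
#'
#' @param path JSON path.
#' @name status_io
#' @export
read_statuses <- function(path) {
  if (!file.exists(path)) stop("status file not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(x, function(s) {
    ab <- NULL
    if (length(s$absences)) {
      ab <- data.frame(
        start = vapply(s$absences, `[[`, character(1), "start"),
        end = vapply(s$absences, `[[`, character(1), "end"),
        reason = vapply(s$absences, `[[`, character(1), "reason"))
    }
    participant_status(s$participant_id, s$group,
                       deceased = s$deceased,
                       living_change = s$living_change,
                       incident = s$incident,
                       absences = ab)
  })
}

#' @param statuses List of [participant_status()] objects.
#' @rdname status_io
#' @export
write_statuses <- function(statuses, path) {
  fmt_date <- function(d) if (is.na(d)) NULL else format(d)
  x <- lapply(statuses, function(s) {
    list(participant_id = s$participant_id,
         group = s$group,
         deceased = fmt_date(s$deceased),
         living_change = fmt_date(s$living_change),
         incident = fmt_date(s$incident),
         absences = if (nrow(s$absences)) lapply(seq_len(nrow(s$absences)),
           function(k) list(start = format(s$absences$start[k]),
                            end = format(s$absences$end[k]),
                            reason = s$absences$reason[k])) else list())
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
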