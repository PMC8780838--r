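#' Analyze one participant's event log
#'
#' The per-participant slice of the pipeline: split into civil days, build
#' and mask daily matrices, average the first `k` valid days into the
#' baseline, compute the percent-difference series, and drop declared
#' absence days.
#'
#' @param log An [event_log()].
#' @param topology The participant's [flat_topology()].
#' @param status Optional [participant_status()] carrying absence intervals.
#' @param k Baseline window in days (default 7).
#' @param diag_weight,offdiag_weight Weight-matrix parameters.
#' @param tz Time zone for day splitting.
#' @return List with `baseline`, `series` (absence-filtered
#'   `difference_series`), `n_days_built`, `n_days_removed`, `n_events`.
#' @export
analyze_participant <- function(log, topology, status = NULL, k = 7,
                                diag_weight = 1, offdiag_weight = 1.5,
                                tz = "UTC") {
  dailies <- daily_matrices(log, topology, mask = TRUE, tz = tz)
  if (length(dailies) < k + 1L)
    stop("participant ", log$participant_id, ": only ", length(dailies),
         " days with events; need more than the baseline window k = ", k)
  W <- make_weight_matrix(topology$n, diag_weight, offdiag_weight)
  baseline <- compute_baseline(dailies, k = k)
  series <- daily_series(baseline, dailies, W,
                         participant_id = log$participant_id)
  n_removed <- 0L
  if (!is.null(status)) {
    series <- filter_absence_days(series, status)
    n_removed <- attr(series, "n_removed")
  }
  list(baseline = baseline, series = series,
       n_days_built = length(dailies),
       n_days_removed = n_removed,
       n_events = nrow(log$events))
}

#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run. Either point the config at
#' existing inputs (`events_dir` with one CSV per participant,
#' `topologies_dir` with `topology_<id>.json`, a statuses JSON and an
#' assessments CSV), or supply a [cohort_spec()] to simulate them first.
#'
#' @param out_dir Output directory for artifacts.
#' @param events_dir,topologies_dir,statuses_path,assessments_path Input
#'   locations (ignored when `cohort` is given).
#' @param cohort Optional [cohort_spec()]; when present the pipeline
#'   simulates its own inputs.
#' @param baseline_days Baseline window k (default 7).
#' @param diag_weight,offdiag_weight Weight matrix parameters (1 / 1.5).
#' @param alpha Significance level for group comparison and bias check.
#' @param group_method Group trend aggregation, `"pooled"` or `"average"`.
#' @param seed Seed recorded in the manifest (the cohort spec's own seed
#'   governs simulation).
#' @param tz Time zone for day splitting.
#' @param write_inputs When simulating, also write the simulated raw inputs
#'   under `out_dir/inputs` (default `FALSE`; event logs are large).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, events_dir = NULL, topologies_dir = NULL,
                       statuses_path = NULL, assessments_path = NULL,
                       cohort = NULL, baseline_days = 7,
                       diag_weight = 1, offdiag_weight = 1.5,
                       alpha = 0.01, group_method = "pooled",
                       seed = 1, tz = "UTC", write_inputs = FALSE) {
  stopifnot(baseline_days >= 1, diag_weight > 0, offdiag_weight > 0,
            alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> validate -> daily graphs -> baseline -> percent
#' difference -> absence filter -> group trends -> signed-rank comparison ->
#' cohort bias check. Writes per-participant baselines and difference
#' series, a trend report, a comparison JSON and a manifest into
#' `config$out_dir`. Outputs are a deterministic function of config +
#' inputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages (default `FALSE`).
#' @return Invisible list with `series`, `group_trend`, `comparison`,
#'   `bias`, `accounting`, and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$cohort)) {
    say("stage simulate: generating cohort (seed ", config$cohort$seed, ")")
    dataset <- simulate_cohort(config$cohort)
    if (isTRUE(config$write_inputs)) {
      ind <- file.path(config$out_dir, "inputs")
      dir.create(file.path(ind, "events"), recursive = TRUE,
                 showWarnings = FALSE)
      for (p in dataset$participants) {
        write_event_log(p$log, file.path(ind, "events",
                                         paste0(p$participant_id, ".csv")))
        write_topology(p$topology, file.path(ind, paste0("topology_", p$participant_id, ".json")))
      }
      write_statuses(lapply(dataset$participants, `[[`, "status"),
                     file.path(ind, "statuses.json"))
      utils::write.csv(dataset$assessments,
                       file.path(ind, "assessments.csv"), row.names = FALSE)
    }
    participants <- dataset$participants
    assessments <- dataset$assessments
  } else {
    for (p in c("events_dir", "topologies_dir", "statuses_path")) {
      if (is.null(config[[p]]) || !file.exists(config[[p]]))
        stop("missing input: ", p)
    }
    statuses <- read_statuses(config$statuses_path)
    names(statuses) <- vapply(statuses, `[[`, character(1), "participant_id")
    files <- list.files(config$events_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (!length(files)) stop("no event logs found in ", config$events_dir)
    participants <- list()
    for (f in files) {
      log <- read_event_log(f, tz = config$tz)
      pid <- log$participant_id
      tf <- file.path(config$topologies_dir,
                      paste0("topology_", pid, ".json"))
      if (!file.exists(tf)) stop("missing topology for ", pid, ": ", tf)
      st <- statuses[[pid]]
      if (is.null(st)) stop("missing status for participant ", pid)
      participants[[pid]] <- list(participant_id = pid, group = st$group,
                                  topology = read_topology(tf), log = log,
                                  status = st)
    }
    assessments <- if (!is.null(config$assessments_path) &&
                       file.exists(config$assessments_path))
      read_assessments(config$assessments_path) else NULL
  }

  say("stage filter: participant exclusion criteria")
  fp <- filter_participants(lapply(participants, `[[`, "status"))
  participants <- participants[names(participants) %in% fp$included_ids]
  if (!length(participants)) stop("no participants left after exclusion")

  say("stage graphs/baseline/diff: ", length(participants), " participants")
  series <- list()
  n_events <- n_days <- n_removed <- 0L
  for (p in participants) {
    res <- analyze_participant(p$log, p$topology, p$status,
                               k = config$baseline_days,
                               diag_weight = config$diag_weight,
                               offdiag_weight = config$offdiag_weight,
                               tz = config$tz)
    series[[p$participant_id]] <- res$series
    n_events <- n_events + res$n_events
    n_days <- n_days + res$n_days_built
    n_removed <- n_removed + res$n_days_removed
    write_adjacency(res$baseline,
                    file.path(config$out_dir,
                              paste0("baseline_", p$participant_id, ".csv")),
                    digits = NA)
    write_difference_series(res$series,
                            file.path(config$out_dir,
                                      paste0("series_", p$participant_id, ".csv")))
  }
  say("  events read: ", n_events, "; days built: ", n_days,
      "; absence days removed: ", n_removed,
      "; participants excluded: ", sum(fp$report$excluded))

  say("stage trend: group least-squares fits (", config$group_method, ")")
  groups <- vapply(participants, `[[`, character(1), "group")
  gt <- group_trend(series, groups, method = config$group_method)

  comparison <- NULL
  gnames <- names(gt$groups)
  if (length(gnames) >= 2L) {
    say("stage compare: signed-rank test over the common window")
    comparison <- compare_group_fits(gt$groups[[gnames[1L]]]$fitted,
                                     gt$groups[[gnames[2L]]]$fitted)
  }

  bias <- NULL
  if (!is.null(assessments)) {
    first <- assessments[!duplicated(assessments$participant_id), ]
    first <- first[first$participant_id %in% names(groups), ]
    ga <- first[groups[first$participant_id] == gnames[1L],
                c("sppb", "tug"), drop = FALSE]
    gb <- first[groups[first$participant_id] == gnames[2L],
                c("sppb", "tug"), drop = FALSE]
    if (nrow(ga) >= 2L && nrow(gb) >= 2L) {
      say("stage bias: cohort disposition check")
      bias <- cohort_bias_check(ga, gb, alpha = config$alpha)
    }
  }

  trend_rows <- do.call(rbind, lapply(gnames, function(g) {
    f <- gt$groups[[g]]$fit
    data.frame(group = g, slope_per_day = f$a, intercept = f$b,
               fitted_change = f$a * gt$window, window_days = gt$window)
  }))
  utils::write.csv(trend_rows, file.path(config$out_dir, "trend_report.csv"),
                   row.names = FALSE)
  if (!is.null(comparison))
    jsonlite::write_json(
      list(W = comparison$W, z = comparison$z, p_value = comparison$p_value,
           n_pairs = comparison$n_pairs, degenerate = comparison$degenerate),
      file.path(config$out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA)

  cfg_plain <- config
  cfg_plain$cohort <- if (!is.null(config$cohort))
    lapply(unclass(config$cohort), function(x)
      if (inherits(x, "Date")) format(x) else x) else NULL
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(lapply(unclass(cfg_plain), function(x)
    if (inherits(x, "Date")) format(x) else x),
    cfg_path, auto_unbox = TRUE, null = "null", digits = NA, force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sensorgraph")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    accounting = list(participants_in = length(fp$report$participant_id),
                      participants_excluded = sum(fp$report$excluded),
                      events_read = n_events, days_built = n_days,
                      absence_days_removed = n_removed,
                      analysis_days = sum(vapply(series, nrow, integer(1)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: artifacts in ", config$out_dir)
  invisible(list(series = series, group_trend = gt, comparison = comparison,
                 bias = bias, accounting = manifest$accounting,
                 manifest = manifest))
}

#' Run the reference synthetic study in memory
#'
#' Simulates the reference cohort (see [cohort_spec()]), analyses every
#' participant, fits the pooled group trends, and compares the fitted
#' daily activity of the two groups -- without writing artifacts. The
#' one-call version of [run_pipeline()] used for recovery checks.
#'
#' @param seed Master seed passed to [cohort_spec()].
#' @param spec A [cohort_spec()]; defaults to the reference conditions
#'   under `seed`.
#' @param k Baseline window (default 7).
#' @return List with `slopes` (named per-group slope per day),
#'   `fitted_change` (slope times the common window), `window`,
#'   `comparison` (a `group_comparison`), `truth` (injected slopes),
#'   `accounting` (days built / removed / analysed), and `group_trend`.
#' @export
reference_study <- function(seed = 1, spec = cohort_spec(seed = seed),
                            k = 7) {
  dataset <- simulate_cohort(spec)
  series <- list()
  n_days <- n_removed <- 0L
  for (p in dataset$participants) {
    res <- analyze_participant(p$log, p$topology, p$status, k = k)
    series[[p$participant_id]] <- res$series
    n_days <- n_days + res$n_days_built
    n_removed <- n_removed + res$n_days_removed
  }
  groups <- vapply(dataset$participants, `[[`, character(1), "group")
  gt <- group_trend(series, groups)
  cmp <- compare_group_fits(gt$groups[["intervention"]]$fitted,
                            gt$groups[["control"]]$fitted)
  slopes <- vapply(gt$groups, function(g) g$fit$a, numeric(1))
  list(slopes = slopes,
       fitted_change = slopes * gt$window,
       window = gt$window,
       comparison = cmp,
       truth = c(intervention = spec$intervention_slope,
                 control = spec$control_slope),
       accounting = list(days_built = n_days,
                         absence_days_removed = n_removed,
                         analysis_days = sum(vapply(series, nrow,
                                                    integer(1)))),
       group_trend = gt)
}
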