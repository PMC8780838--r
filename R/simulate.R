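#' Generate a synthetic flat topology
#'
#' Builds a connected room graph with a hub room (the hallway when present)
#' adjacent to every other room, plus random extra connections between
#' non-hub rooms. A bedroom-bathroom direct connection is never created, so
#' any flat containing both rooms has at least one physically impossible
#' transition. One PIR sensor per room, plus a redundant second sensor in
#' the hub.
#'
#' @param n_rooms Number of rooms (>= 1); 5 gives the classic flat
#'   (living room, bedroom, kitchen, bathroom, hallway).
#' @param seed Integer seed; the same seed always yields the same topology.
#' @param p_extra Probability of each eligible extra non-hub connection
#'   (default 0.3).
#' @return A [flat_topology()].
#' @export
generate_topology <- function(n_rooms = 5, seed = 1, p_extra = 0.3) {
  if (n_rooms < 1L) stop("need at least one room")
  pool <- c("living room", "bedroom", "kitchen", "bathroom", "hallway",
            "study", "storage", "dining room", "balcony", "utility room")
  rooms <- if (n_rooms <= length(pool)) pool[seq_len(n_rooms)] else
    c(pool, paste0("room ", seq_len(n_rooms - length(pool))))
  hub <- if ("hallway" %in% rooms) "hallway" else rooms[1L]
  conns <- list()
  for (r in setdiff(rooms, hub))
    conns[[length(conns) + 1L]] <- c(hub, r)
  others <- setdiff(rooms, hub)
  set.seed(as.integer(seed))
  if (length(others) > 1L) {
    for (i in seq_len(length(others) - 1L)) for (j in (i + 1L):length(others)) {
      pair <- sort(c(others[i], others[j]))
      if (identical(pair, c("bathroom", "bedroom"))) next
      if (stats::runif(1) < p_extra)
        conns[[length(conns) + 1L]] <- c(others[i], others[j])
    }
  }
  sens <- paste0("pir_", gsub(" ", "_", rooms))
  names(rooms) <- NULL
  sensors <- stats::setNames(rooms, sens)
  sensors <- c(sensors, stats::setNames(hub, paste0("pir_", gsub(" ", "_", hub), "_2")))
  flat_topology(rooms, sensors, conns)
}

#' Resident movement and emission model
#'
#' A lone resident moves between connected rooms as a semi-Markov process:
#' dwell in the current room for a log-normal time, then move to a connected
#' room with probability proportional to the destination's attractiveness.
#' The room's PIR sensor fires on entry and then at a Poisson re-trigger
#' rate while the resident is present; emitted events are thinned so that no
#' sensor fires twice within its cool-down. Nights are spent in the bedroom
#' with a low re-trigger rate.
#'
#' @param topology A [flat_topology()].
#' @param dwell_mean Named numeric vector, mean dwell per visit in minutes
#'   by room; unnamed rooms use `default_dwell`.
#' @param dwell_sdlog Log-scale SD of the log-normal dwell time
#'   (default 0.6).
#' @param retrigger_rate Named numeric, sensor re-trigger rate in events per
#'   minute of presence by room; unnamed rooms use `default_rate`. 0 gives
#'   entry-only emission.
#' @param attract Named numeric, relative attractiveness of each room as a
#'   move destination; unnamed rooms use 0.15.
#' @param default_dwell,default_rate Fallbacks for rooms without a named
#'   value.
#' @param wake_hour,sleep_hour Active window bounds (decimal hours).
#' @param night_room Room occupied overnight (default `"bedroom"` if
#'   present, else the first room).
#' @param night_rate Overnight re-trigger rate, events per minute.
#' @param aux_share Probability that an event in a room with a redundant
#'   sensor is attributed to the redundant one (default 0.3).
#' @return Object of class `resident_model`.
#' @export
resident_model <- function(topology,
                           dwell_mean = c("living room" = 25, "bedroom" = 15,
                                          "kitchen" = 12, "bathroom" = 6,
                                          "hallway" = 1.5),
                           dwell_sdlog = 0.6,
                           retrigger_rate = c("living room" = 0.6,
                                              "bedroom" = 0.4,
                                              "kitchen" = 0.7,
                                              "bathroom" = 0.7,
                                              "hallway" = 0.3),
                           attract = c("living room" = 0.45, "kitchen" = 0.25,
                                       "bedroom" = 0.15, "bathroom" = 0.15,
                                       "hallway" = 0.25),
                           default_dwell = 10, default_rate = 0.5,
                           wake_hour = 6.5, sleep_hour = 22.5,
                           night_room = NULL, night_rate = 0.05,
                           aux_share = 0.3) {
  stopifnot(inherits(topology, "flat_topology"))
  rooms <- topology$rooms
  n <- topology$n
  pick <- function(named, fallback) {
    v <- rep(fallback, n)
    hit <- match(rooms, names(named))
    v[!is.na(hit)] <- named[hit[!is.na(hit)]]
    stats::setNames(v, rooms)
  }
  dm <- pick(dwell_mean, default_dwell)
  rr <- pick(retrigger_rate, default_rate)
  at <- pick(attract, 0.15)
  if (any(dm <= 0)) stop("dwell means must be positive")
  if (any(rr < 0) || night_rate < 0) stop("re-trigger rates must be >= 0")
  if (is.null(night_room))
    night_room <- if ("bedroom" %in% rooms) "bedroom" else rooms[1L]
  if (!(night_room %in% rooms)) stop("unknown night room: ", night_room)
  # transition rows: attractiveness-weighted over connected distinct rooms;
  # zero on impossible transitions by construction
  P <- matrix(0, n, n, dimnames = list(rooms, rooms))
  for (i in seq_len(n)) {
    nb <- which(topology$transitions[i, ] & seq_len(n) != i)
    if (length(nb)) P[i, nb] <- at[nb] / sum(at[nb])
  }
  structure(list(topology = topology, dwell_mean = dm,
                 dwell_sdlog = dwell_sdlog, retrigger_rate = rr,
                 attract = at, transition_prob = P,
                 wake_hour = wake_hour, sleep_hour = sleep_hour,
                 night_room = night_room, night_rate = night_rate,
                 aux_share = aux_share),
            class = "resident_model")
}

#' Simulate one participant's event log
#'
#' Runs the [resident_model()] day by day. Daily activity scales
#' multiplicatively with `f(t) = multiplier * max(0, 1 + slope * t)`
#' (t = 0-based study day): movement initiation (1/dwell) and re-trigger
#' rates are both multiplied by f, so the expected daily event count is
#' proportional to f and the injected slope is recoverable from the event
#' stream. Absence days emit nothing.
#'
#' @param model A [resident_model()].
#' @param days Number of study days (>= 1).
#' @param seed Integer seed.
#' @param slope Fractional activity change per day (e.g. -0.001 means one
#'   per-mille less activity each day).
#' @param multiplier Participant-level baseline rate multiplier.
#' @param absence_dates Dates (or 0-based day indices) on which the flat is
#'   empty.
#' @param start_date First study day (Date).
#' @param participant_id Identifier stored on the log.
#' @param cooldown Sensor cool-down in seconds (default 8); emitted events
#'   are thinned to respect it.
#' @param tz Time zone of the emitted timestamps.
#' @return List with `log` (an [event_log()]) and `truth`: injected slope
#'   and multiplier, absence dates, and `daily_events` (named per-date count
#'   of emitted events after thinning).
#' @export
simulate_participant <- function(model, days, seed, slope = 0,
                                 multiplier = 1, absence_dates = NULL,
                                 start_date = as.Date("2020-10-01"),
                                 participant_id = "p1", cooldown = 8,
                                 tz = "UTC") {
  stopifnot(inherits(model, "resident_model"), days >= 1L)
  set.seed(as.integer(seed))
  topo <- model$topology
  n <- topo$n
  rooms <- topo$rooms
  night <- match(model$night_room, rooms)
  # shortest connected route to the night room from every start, for the
  # bedtime walk (BFS over the possible-transition graph)
  paths_to_night <- bfs_paths_to(topo$transitions, night)
  wake <- model$wake_hour * 3600
  sleep <- model$sleep_hour * 3600
  sdl <- model$dwell_sdlog
  dwell_sec <- 60 * model$dwell_mean * exp(-0.5 * sdl^2)  # median-adjusted
  lam_min <- model$retrigger_rate
  # neighbour lists + cumulative transition probabilities
  nbrs <- lapply(seq_len(n), function(i) which(model$transition_prob[i, ] > 0))
  cumw <- lapply(seq_len(n), function(i)
    cumsum(model$transition_prob[i, nbrs[[i]]]))
  if (inherits(absence_dates, "Date")) {
    absent_idx <- as.numeric(absence_dates - start_date)
  } else absent_idx <- as.numeric(absence_dates)
  absent <- rep(FALSE, days)
  ok <- absent_idx >= 0 & absent_idx < days
  absent[absent_idx[ok] + 1] <- TRUE

  if (!all(rooms %in% topo$sensors))
    stop("every room needs at least one sensor to simulate emission")
  v_room <- vector("list", days); v_entry <- v_room; v_dur <- v_room
  v_is_entry <- v_room
  for (d in seq_len(days)) {
    if (absent[d]) next
    f <- multiplier * max(0, 1 + slope * (d - 1))
    if (f <= 0) next
    day0 <- (d - 1) * 86400
    nz <- 256L
    zb <- stats::rnorm(nz); ub <- stats::runif(nz)
    cur <- night
    time <- wake
    rr <- er <- dr <- numeric(nz); ie <- logical(nz)
    vi <- 0L
    while (time < sleep) {
      vi <- vi + 1L
      if (vi > length(zb)) {
        zb <- c(zb, stats::rnorm(nz)); ub <- c(ub, stats::runif(nz))
        rr <- c(rr, numeric(nz)); er <- c(er, numeric(nz))
        dr <- c(dr, numeric(nz)); ie <- c(ie, logical(nz))
      }
      dw <- dwell_sec[cur] / f * exp(sdl * zb[vi])
      dur <- min(dw, sleep - time)
      rr[vi] <- cur; er[vi] <- day0 + time; dr[vi] <- dur; ie[vi] <- TRUE
      time <- time + dw
      nb <- nbrs[[cur]]
      if (!length(nb)) { time <- sleep; dr[vi] <- sleep - (er[vi] - day0); break }
      cur <- nb[findInterval(ub[vi], cumw[[cur]]) + 1L]
    }
    rr <- rr[seq_len(vi)]; er <- er[seq_len(vi)]; dr <- dr[seq_len(vi)]
    ie <- ie[seq_len(vi)]
    # walk to the night room at bedtime along a physically possible route,
    # starting from the last room actually visited
    bed_t <- sleep
    last_room <- rr[vi]
    if (last_room != night) {
      for (step in paths_to_night[[last_room]]) {
        rr <- c(rr, step); er <- c(er, day0 + bed_t); dr <- c(dr, 0)
        ie <- c(ie, TRUE); bed_t <- bed_t + 30
      }
    }
    # overnight occupancy of the night room (morning + evening intervals)
    rr <- c(rr, night, night)
    er <- c(er, day0, day0 + bed_t)
    dr <- c(dr, wake, 86400 - bed_t)
    ie <- c(ie, FALSE, FALSE)
    v_room[[d]] <- rr; v_entry[[d]] <- er; v_dur[[d]] <- dr
    v_is_entry[[d]] <- ie
  }
  room <- unlist(v_room); entry <- unlist(v_entry); dur <- unlist(v_dur)
  is_entry <- unlist(v_is_entry)
  if (is.null(room)) room <- integer()
  # Poisson re-trigger events within each occupancy interval
  day_of <- floor(entry / 86400)
  f_day <- multiplier * pmax(0, 1 + slope * day_of)
  lam <- dur / 60 * ifelse(is_entry | room != night | dur < 1,
                           lam_min[room], model$night_rate) * f_day
  lam[dur <= 0] <- 0
  k <- stats::rpois(length(lam), lam)
  K <- sum(k)
  ev_time <- c(entry[is_entry],
               rep(entry, k) + stats::runif(K) * rep(dur, k))
  ev_room <- c(room[is_entry], rep(room, k))
  o <- order(ev_time)
  ev_time <- ev_time[o]; ev_room <- ev_room[o]
  # sensor attribution: redundant sensors share their room's events
  room_sensors <- split(names(topo$sensors), match(topo$sensors, rooms))
  primary <- vapply(seq_len(n), function(i)
    room_sensors[[as.character(i)]][1L], character(1))
  aux <- vapply(seq_len(n), function(i) {
    s <- room_sensors[[as.character(i)]]
    if (length(s) > 1L) s[2L] else NA_character_
  }, character(1))
  sid <- primary[ev_room]
  if (any(!is.na(aux))) {
    u <- stats::runif(length(ev_room))
    swap <- !is.na(aux[ev_room]) & u < model$aux_share
    sid[swap] <- aux[ev_room[swap]]
  }
  # cool-down thinning: keep an event only if >= cooldown after the previous
  # raw event of the same sensor (guarantees kept-event gaps >= cooldown)
  keep <- rep(TRUE, length(ev_time))
  for (idx in split(seq_along(sid), sid)) {
    if (length(idx) > 1L)
      keep[idx[-1L][diff(ev_time[idx]) < cooldown]] <- FALSE
  }
  ev_time <- ev_time[keep]; sid <- sid[keep]
  origin <- as.POSIXct(paste(start_date, "00:00:00"), tz = tz)
  log <- event_log(participant_id,
                   data.frame(timestamp = origin + ev_time,
                              sensor_id = sid),
                   sort = FALSE)
  daily <- tabulate(floor(ev_time / 86400) + 1, nbins = days)
  names(daily) <- format(start_date + 0:(days - 1))
  list(log = log,
       truth = list(slope = slope, multiplier = multiplier,
                    absence_dates = start_date + which(absent) - 1,
                    daily_events = daily))
}

#' Cohort specification for the synthetic study
#'
#' Defines the reference study conditions: 9 intervention and 6 control
#' participants observed for 310 calendar days, with on average ~7.5 absence
#' days per participant (vacation, short-term care, hospitalization), an
#' essentially flat intervention activity trend (-1e-4 per day) against a
#' declining control trend (-1e-3 per day), log-normal between-participant
#' rate heterogeneity, and monthly SPPB/TUG assessments whose fitted changes
#' mirror a small capacity improvement in both groups.
#'
#' @param n_intervention,n_control Group sizes.
#' @param study_days Calendar length of the study in days.
#' @param intervention_slope,control_slope Injected fractional activity
#'   change per day.
#' @param multiplier_sdlog Log-SD of the participant rate multiplier.
#' @param absence_mean_intervals Poisson mean number of absence intervals
#'   per participant.
#' @param absence_mean_duration Mean absence interval length in days
#'   (1 + Poisson(mean - 1)).
#' @param visitor_rate Spurious visitor events per day added via
#'   [inject_visitor_noise()]; 0 (default) models a strictly lone resident.
#' @param n_rooms Rooms per flat.
#' @param sppb_change,tug_change Named (`intervention`, `control`) total
#'   change of the assessment scores across the study.
#' @param assessment_interval Days between assessments (default 30).
#' @param start_date First study day.
#' @param seed Master seed; fully determines the cohort.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_intervention = 9, n_control = 6,
                        study_days = 310,
                        intervention_slope = -1e-4,
                        control_slope = -1e-3,
                        multiplier_sdlog = 0.3,
                        absence_mean_intervals = 1.5,
                        absence_mean_duration = 5,
                        visitor_rate = 0,
                        n_rooms = 5,
                        sppb_change = c(intervention = 0.16, control = 0.06),
                        tug_change = c(intervention = -0.10, control = -0.08),
                        assessment_interval = 30,
                        start_date = as.Date("2020-10-01"),
                        seed = 1) {
  stopifnot(n_intervention >= 0, n_control >= 0, study_days >= 1,
            visitor_rate >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a full synthetic cohort
#'
#' Generates, per participant: a flat topology, a resident model, an event
#' log with injected group activity slope and personal rate multiplier, a
#' status record carrying the absence calendar, and monthly assessment
#' records. Everything is a deterministic function of the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `participants` (each: `participant_id`, `group`,
#'   `topology`, `log`, `status`, `truth`), `assessments` (one data.frame),
#'   and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- spec$n_intervention + spec$n_control
  if (n_tot == 0L)
    return(list(participants = list(),
                assessments = data.frame(participant_id = character(),
                                         date = as.Date(character()),
                                         sppb = numeric(), tug = numeric()),
                spec = spec))
  set.seed(as.integer(spec$seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_tot * 2L)
  groups <- rep(c("intervention", "control"),
                c(spec$n_intervention, spec$n_control))
  participants <- vector("list", n_tot)
  assess <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    pid <- sprintf("p%02d", i)
    g <- groups[i]
    set.seed(seeds[i])
    topo <- generate_topology(spec$n_rooms, seed = seeds[i])
    set.seed(seeds[i] %% 1000003L + 7L)
    mult <- exp(stats::rnorm(1, 0, spec$multiplier_sdlog) -
                  0.5 * spec$multiplier_sdlog^2)
    # absence calendar: a few non-overlapping intervals
    n_abs <- stats::rpois(1, spec$absence_mean_intervals)
    ab <- NULL
    if (n_abs > 0) {
      starts <- sort(sample.int(spec$study_days, n_abs))
      durs <- 1 + stats::rpois(n_abs, max(0, spec$absence_mean_duration - 1))
      ends <- pmin(starts + durs - 1, spec$study_days)
      keep <- rep(TRUE, n_abs)  # drop intervals swallowed by the previous one
      if (n_abs > 1) for (j in 2:n_abs) {
        prev <- max(which(keep[seq_len(j - 1)]))
        if (starts[j] <= ends[prev] + 1) {
          ends[prev] <- max(ends[prev], ends[j]); keep[j] <- FALSE
        }
      }
      ab <- data.frame(
        start = spec$start_date + starts[keep] - 1,
        end = spec$start_date + ends[keep] - 1,
        reason = sample(c("vacation", "short-term care", "hospitalization"),
                        sum(keep), replace = TRUE))
    }
    abs_dates <- as.Date(character())
    if (!is.null(ab)) abs_dates <- do.call(c, lapply(seq_len(nrow(ab)),
      function(k) seq(ab$start[k], ab$end[k], by = "day")))
    slope <- if (g == "intervention") spec$intervention_slope else
      spec$control_slope
    model <- resident_model(topo)
    sim <- simulate_participant(model, spec$study_days,
                                seed = seeds[n_tot + i],
                                slope = slope, multiplier = mult,
                                absence_dates = abs_dates,
                                start_date = spec$start_date,
                                participant_id = pid)
    if (spec$visitor_rate > 0) {
      vn <- inject_visitor_noise(sim$log, topo, spec$visitor_rate,
                                 seed = seeds[n_tot + i] %% 999983L + 11L)
      sim$log <- vn$log
      sim$truth$visitor_indices <- vn$indices
    } else sim$truth$visitor_indices <- integer()
    status <- participant_status(pid, g, absences = ab)
    # monthly assessments: linear capacity trend + noise, bounded
    a_day <- seq(0, spec$study_days - 1, by = spec$assessment_interval)
    frac <- a_day / max(1, spec$study_days - 1)
    sppb0 <- sample(4:9, 1)
    tug0 <- stats::rlnorm(1, log(16), 0.2)
    sppb <- round(sppb0 + spec$sppb_change[[g]] * frac +
                    stats::rnorm(length(frac), 0, 0.5))
    sppb <- pmin(12, pmax(0, sppb))
    tug <- pmax(2, tug0 + spec$tug_change[[g]] * frac +
                  stats::rnorm(length(frac), 0, 0.4))
    assess[[i]] <- data.frame(participant_id = pid,
                              date = spec$start_date + a_day,
                              sppb = sppb, tug = round(tug, 2))
    participants[[i]] <- list(participant_id = pid, group = g,
                              topology = topo, log = sim$log,
                              status = status, truth = sim$truth)
  }
  names(participants) <- vapply(participants, `[[`, character(1),
                                "participant_id")
  list(participants = participants,
       assessments = do.call(rbind, assess),
       spec = spec)
}

#' Inject visitor contamination into an event log
#'
#' Adds spurious events at a Poisson daily rate, placed uniformly in time
#' and over rooms, so some of them form physically impossible transitions --
#' the signature of a second person the masking step is meant to absorb.
#'
#' @param log An [event_log()].
#' @param topology The flat's [flat_topology()].
#' @param rate Expected spurious events per day (>= 0).
#' @param seed Integer seed.
#' @return List with `log` (contaminated, re-sorted) and `indices` (row
#'   positions of the injected events in the contaminated log).
#' @export
inject_visitor_noise <- function(log, topology, rate, seed = 1) {
  stopifnot(inherits(log, "event_log"), rate >= 0)
  if (rate == 0 || nrow(log$events) == 0L)
    return(list(log = log, indices = integer()))
  set.seed(as.integer(seed))
  t0 <- min(log$events$timestamp)
  t1 <- max(log$events$timestamp)
  span_days <- max(1, as.numeric(difftime(t1, t0, units = "days")))
  K <- stats::rpois(1, rate * span_days)
  if (K == 0) return(list(log = log, indices = integer()))
  times <- t0 + stats::runif(K) * as.numeric(difftime(t1, t0, units = "secs"))
  rooms <- sample(topology$rooms, K, replace = TRUE)
  prim <- names(topology$sensors)[match(rooms, topology$sensors)]
  add <- data.frame(timestamp = times, sensor_id = prim)
  comb <- rbind(cbind(log$events, injected = FALSE),
                cbind(add, injected = TRUE))
  o <- order(comb$timestamp)
  comb <- comb[o, , drop = FALSE]
  out <- event_log(log$participant_id,
                   comb[, c("timestamp", "sensor_id")], sort = FALSE)
  list(log = out, indices = which(comb$injected))
}

# BFS shortest paths to a target room over the possible-transition graph;
# returns, per start room, the vector of rooms to step through (start
# excluded, target included). Empty path if start == target or unreachable.
bfs_paths_to <- function(trans, target) {
  n <- nrow(trans)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[target] <- TRUE
  queue <- target
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(trans[, v] & !seen)  # rooms that can step INTO v
    seen[nb] <- TRUE
    prev[nb] <- v
    queue <- c(queue, nb)
  }
  lapply(seq_len(n), function(s) {
    if (s == target || !seen[s]) return(integer())
    path <- integer()
    v <- s
    while (v != target) { v <- prev[v]; path <- c(path, v) }
    path
  })
}
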