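# Shared fixtures, all built in code.

# Five-room flat in the style of the printed example: a direct
# bedroom <-> bathroom transition is physically impossible, everything else
# is connected.
flat5 <- function() {
  rooms <- c("bedroom", "bathroom", "kitchen", "living room", "hallway")
  conns <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    pair <- sort(c(rooms[i], rooms[j]))
    if (identical(pair, c("bathroom", "bedroom"))) next
    conns[[length(conns) + 1L]] <- c(rooms[i], rooms[j])
  }
  flat_topology(rooms,
                sensors = stats::setNames(rooms, paste0("s_", gsub(" ", "_", rooms))),
                connections = conns)
}

# Reference baseline matrix (one-week mean) of the example participant.
baseline_example <- function() {
  rooms <- c("bedroom", "bathroom", "kitchen", "living room", "hallway")
  adjacency_matrix(matrix(c(
    45.14, 0,      0.14,   34.84,  1.86,
    0,     114.29, 0,      1,      22.86,
    0,     0,      144.86, 38.14,  0.43,
    35.14, 1.29,   38.43,  294.43, 50.71,
    1.71,  19.57,  0.14,   51.86,  70
  ), 5, 5, byrow = TRUE), rooms)
}

# The example participant's random-day matrix.
day_example <- function() {
  rooms <- c("bedroom", "bathroom", "kitchen", "living room", "hallway")
  adjacency_matrix(matrix(c(
    45, 0,  0,   34,  1,
    0,  98, 0,   1,   25,
    0,  0,  196, 39,  1,
    32, 1,  39,  230, 68,
    3,  25, 1,   66,  64
  ), 5, 5, byrow = TRUE), rooms)
}

# independent 25-cell loop oracle for the weighted difference
diff_oracle <- function(B, D, diag_w = 1, offdiag_w = 1.5) {
  n <- nrow(B)
  s <- 0
  den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- if (i == j) diag_w else offdiag_w
    s <- s + w * (B[i, j] - D[i, j])
    den <- den + w * B[i, j]
  }
  list(diff = s, pd = s / den, denom = den)
}

# brute-force pair tally oracle: walks the event stream one pair at a time
tally_oracle <- function(room_idx, n) {
  A <- matrix(0, n, n)
  if (length(room_idx) >= 2) {
    for (k in seq_len(length(room_idx) - 1)) {
      A[room_idx[k], room_idx[k + 1]] <- A[room_idx[k], room_idx[k + 1]] + 1
    }
  }
  A
}

# closed-form normal-equations oracle for the straight-line fit
normal_eq_oracle <- function(t, y) {
  n <- length(t)
  a <- (n * sum(t * y) - sum(t) * sum(y)) / (n * sum(t^2) - sum(t)^2)
  b <- (sum(y) - a * sum(t)) / n
  c(a = a, b = b)
}

# event-log data.frame from day-second offsets and sensor ids
make_events <- function(secs, sensors, origin = "2021-03-01") {
  data.frame(
    timestamp = as.POSIXct(paste(origin, "00:00:00"), tz = "UTC") + secs,
    sensor_id = sensors)
}

# a tiny deterministic difference series spanning consecutive dates
make_series <- function(pd, start = as.Date("2021-03-08"), pid = "p1") {
  structure(data.frame(date = start + seq_along(pd) - 1, pd = pd),
            class = c("difference_series", "data.frame"),
            participant_id = pid)
}
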