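#' Flat topology
#'
#' Describes one flat: its rooms (the vertex set of the sensor graph, in a
#' fixed order that defines adjacency-matrix row/column order), the mapping
#' from PIR sensor identifiers to rooms, and the set of ordered room pairs
#' that are physically reachable by a direct transition. Loops (a room to
#' itself) are always possible: repeated motion in one room is real movement.
#'
#' @param rooms Character vector of unique room names. Their order fixes the
#'   row/column order of every adjacency matrix built for this flat.
#' @param sensors Named character vector mapping sensor id (name) to room
#'   (value). Several sensors may map to the same room; events from all of
#'   them collapse onto that room's vertex.
#' @param connections Two-column matrix or data.frame (or list of length-2
#'   character vectors) of undirected room-room connections. Each is expanded
#'   to both ordered pairs. Loops are added automatically and need not be
#'   listed.
#' @return An object of class `flat_topology`: a list with elements `rooms`,
#'   `n`, `sensors`, and `transitions` (an n x n logical matrix, `TRUE` where
#'   the ordered transition row -> column is physically possible).
#' @export
flat_topology <- function(rooms, sensors, connections = NULL) {
  rooms <- as.character(rooms)
  if (length(rooms) < 1L) stop("a flat needs at least one room")
  if (anyDuplicated(rooms)) stop("duplicate room name: ",
                                 rooms[duplicated(rooms)][1L])
  sensors <- unlist(sensors)
  if (length(sensors)) {
    if (is.null(names(sensors)) || any(names(sensors) == ""))
      stop("every sensor needs an id (names of 'sensors')")
    if (anyDuplicated(names(sensors)))
      stop("sensor mapped more than once: ",
           names(sensors)[duplicated(names(sensors))][1L])
    bad <- setdiff(unique(sensors), rooms)
    if (length(bad)) stop("sensor mapped to unlisted room: ",
                          paste(bad, collapse = ", "))
  }
  n <- length(rooms)
  trans <- matrix(FALSE, n, n, dimnames = list(rooms, rooms))
  diag(trans) <- TRUE
  if (is.list(connections) && !is.data.frame(connections))
    connections <- do.call(rbind, connections)
  if (!is.null(connections) && length(connections)) {
    connections <- as.matrix(connections)
    if (length(connections) && ncol(connections) != 2L)
      stop("connections must have two columns (roomA, roomB)")
    for (k in seq_len(nrow(connections))) {
      a <- match(connections[k, 1L], rooms)
      b <- match(connections[k, 2L], rooms)
      if (is.na(a) || is.na(b))
        stop("connection references unknown room: ",
             paste(connections[k, ], collapse = " -- "))
      trans[a, b] <- TRUE
      trans[b, a] <- TRUE
    }
  }
  structure(list(rooms = rooms, n = n, sensors = sensors,
                 transitions = trans),
            class = "flat_topology")
}

#' @export
print.flat_topology <- function(x, ...) {
  cat("<flat_topology> ", x$n, " rooms: ",
      paste(x$rooms, collapse = ", "), "\n", sep = "")
  cat("  sensors: ", length(x$sensors),
      "; possible ordered transitions: ", sum(x$transitions), "\n", sep = "")
  invisible(x)
}

#' Read a flat topology from JSON
#'
#' Expected schema:
#' `{"rooms": [...], "sensors": {"<id>": "<room>"},
#'   "connections": [["roomA","roomB"], ...]}`.
#' Connections are undirected in the file and expanded to both ordered pairs;
#' loops are always added.
#'
#' @param path Path to a JSON file.
#' @return A [flat_topology()] object.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  conns <- x$connections
  if (!is.null(conns) && is.list(conns)) conns <- do.call(rbind, conns)
  flat_topology(rooms = x$rooms, sensors = unlist(x$sensors),
                connections = conns)
}

#' Write a flat topology to JSON
#'
#' Inverse of [read_topology()]. Loops are not written (they are implied);
#' each undirected connection is written once.
#'
#' @param topology A [flat_topology()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "flat_topology"))
  tr <- topology$transitions
  conns <- list()
  n <- topology$n
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (tr[i, j]) conns[[length(conns) + 1L]] <-
          c(topology$rooms[i], topology$rooms[j])
    }
  }
  out <- list(rooms = topology$rooms,
              sensors = as.list(topology$sensors),
              connections = conns)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# room index for each sensor id; errors on unknown sensors
sensor_room_index <- function(sensor_id, topology) {
  room <- topology$sensors[as.character(sensor_id)]
  if (anyNA(room)) {
    bad <- unique(as.character(sensor_id)[is.na(room)])
    stop("unknown sensor id(s): ", paste(bad, collapse = ", "))
  }
  match(room, topology$rooms)
}
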