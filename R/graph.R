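#' Adjacency matrix constructor
#'
#' The sensor graph is a weighted directed multigraph over the rooms of a
#' flat; its adjacency matrix A has A\[i, j\] equal to the number of observed
#' transitions from room i (row) to room j (column). The diagonal counts
#' motion within a room (loops). All downstream statistics operate on this
#' representation.
#'
#' @param values n x n numeric matrix with nonnegative entries.
#' @param labels Room names; default taken from `dimnames(values)`.
#' @return A plain numeric matrix with room dimnames (class
#'   `adjacency_matrix` prepended for printing).
#' @export
adjacency_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("adjacency matrix must be square")
  if (any(values < 0)) stop("adjacency entries must be nonnegative")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) stop("room labels are required")
  if (length(labels) != nrow(values))
    stop("label count does not match matrix dimension")
  values <- matrix(as.numeric(values), nrow(values),
                   dimnames = list(labels, labels))
  class(values) <- c("adjacency_matrix", class(values))
  values
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  y <- x
  class(y) <- "matrix"
  print(round(unclass(y), 2), ...)
  invisible(x)
}

#' Single-transition edge-weight update
#'
#' Adds 1 to entry (i, j): the elementary update applied once per observed
#' consecutive sensor-event pair when a daily graph is accumulated.
#'
#' @param G Adjacency matrix.
#' @param i,j Source and destination room, as 1-based index or room name.
#' @return `G` with entry (i, j) incremented by 1.
#' @export
apply_edge_update <- function(G, i, j) {
  n <- nrow(G)
  if (is.character(i)) i <- match(i, rownames(G))
  if (is.character(j)) j <- match(j, colnames(G))
  if (is.na(i) || is.na(j) || i < 1L || i > n || j < 1L || j > n)
    stop("edge update index out of range")
  G[i, j] <- G[i, j] + 1
  G
}

#' Build the daily adjacency matrix from one day's events
#'
#' Every consecutive pair of events contributes 1 to the edge from the first
#' event's room to the second's, so a day with m events yields a matrix with
#' total mass m - 1. Same-room pairs land on the diagonal (loops). No masking
#' is applied here; see [mask_impossible()].
#'
#' @param day A `day_events` element from [split_by_day()], or an
#'   [event_log()] (all its events are used).
#' @param topology A [flat_topology()]; defines labels, order, and the
#'   sensor-to-room mapping.
#' @return An [adjacency_matrix()] of transition counts.
#' @export
build_daily_matrix <- function(day, topology) {
  stopifnot(inherits(topology, "flat_topology"))
  ev <- if (inherits(day, "event_log")) day$events else day$events
  n <- topology$n
  A <- matrix(0, n, n, dimnames = list(topology$rooms, topology$rooms))
  m <- nrow(ev)
  if (m >= 2L) {
    r <- sensor_room_index(ev$sensor_id, topology)
    from <- r[-m]
    to <- r[-1L]
    counts <- tabulate(from + (to - 1L) * n, nbins = n * n)
    A <- matrix(counts, n, n, dimnames = dimnames(A))
  } else if (m == 1L) {
    # single event: no pair, zero matrix, but still checks the sensor id
    sensor_room_index(ev$sensor_id, topology)
  }
  adjacency_matrix(A)
}

#' Zero the entries of physically impossible transitions
#'
#' An ordered room pair absent from the flat's `possible_transitions` cannot
#' be walked directly by the resident; counts landing there come from
#' visitors, sensor glitches, or missed intermediate firings, and are fixed
#' to 0. The removed mass is kept as the `"masked_mass"` attribute.
#' Masking is idempotent.
#'
#' @param A An [adjacency_matrix()] whose labels equal `topology$rooms`.
#' @param topology A [flat_topology()].
#' @return The masked matrix, with attributes `masked_mass` (total weight
#'   zeroed) and `masked_pairs` (number of nonzero cells zeroed).
#' @export
mask_impossible <- function(A, topology) {
  stopifnot(inherits(topology, "flat_topology"))
  if (!identical(rownames(A), topology$rooms))
    stop("matrix labels do not match topology rooms")
  drop <- !topology$transitions & unclass(A) != 0
  masked_mass <- sum(A[drop])
  A[!topology$transitions] <- 0
  attr(A, "masked_mass") <- masked_mass
  attr(A, "masked_pairs") <- sum(drop)
  A
}

#' Build masked daily matrices for a whole log
#'
#' Convenience wrapper: [split_by_day()], then [build_daily_matrix()] and
#' (by default) [mask_impossible()] per day.
#'
#' @inheritParams split_by_day
#' @param topology A [flat_topology()].
#' @param mask Apply [mask_impossible()] to each day (default `TRUE`).
#' @return Named list (ISO dates) of adjacency matrices.
#' @export
daily_matrices <- function(log, topology, mask = TRUE, tz = "UTC") {
  days <- split_by_day(log, tz = tz)
  lapply(days, function(d) {
    A <- build_daily_matrix(d, topology)
    if (mask) A <- mask_impossible(A, topology) else A
    A
  })
}

#' Read / write an adjacency matrix as labelled CSV
#'
#' First column and header row carry the room labels; cells are numeric.
#'
#' @param path CSV path.
#' @param digits Decimal places written (default 2); `NA` writes full
#'   precision.
#' @name adjacency_io
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("adjacency CSV is not square: ", nrow(m), " x ", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("adjacency CSV row and column labels differ")
  adjacency_matrix(m)
}

#' @param A An [adjacency_matrix()].
#' @rdname adjacency_io
#' @export
write_adjacency <- function(A, path, digits = 2) {
  vals <- unclass(A)
  out <- if (is.na(digits)) vals else round(vals, digits)
  df <- as.data.frame(out)
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Graph view of an adjacency matrix
#'
#' Converts the matrix to an igraph weighted directed graph (one edge per
#' ordered room pair with positive weight, loops allowed), or back. The two
#' views are lossless inverses.
#'
#' @param A An [adjacency_matrix()].
#' @return For `sensor_graph()`, an `igraph` object; for
#'   `adjacency_from_graph()`, an [adjacency_matrix()].
#' @export
sensor_graph <- function(A) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for the graph view")
  igraph::graph_from_adjacency_matrix(unclass(A), mode = "directed",
                                      weighted = TRUE, diag = TRUE)
}

#' @param g An igraph object produced by [sensor_graph()].
#' @rdname sensor_graph
#' @export
adjacency_from_graph <- function(g) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for the graph view")
  m <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  adjacency_matrix(m)
}
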