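#' Baseline adjacency matrix
#'
#' The baseline B is the entrywise mean of the first k valid daily matrices
#' of a participant, taken at the start of observation; every later day D is
#' scored against it. k = 7 by default: a one-week window covers the weekly
#' routine cycle, and the printed reference baseline shows cell values at
#' multiples of 1/7.
#'
#' @param dailies List of daily [adjacency_matrix()] objects with identical
#'   labels, ordered by date (names are used as provenance dates if present).
#' @param k Window length in days (default 7).
#' @return The baseline [adjacency_matrix()], with attributes
#'   `baseline_dates` (contributing dates, if known) and `k`.
#' @export
compute_baseline <- function(dailies, k = 7) {
  if (k < 1L) stop("baseline window must be at least 1 day")
  if (length(dailies) < k)
    stop("insufficient data: need ", k, " daily matrices, have ",
         length(dailies))
  first <- dailies[seq_len(k)]
  labs <- rownames(first[[1L]])
  for (d in first)
    if (!identical(rownames(d), labs))
      stop("daily matrices have inconsistent labels")
  B <- Reduce(`+`, lapply(first, unclass)) / k
  B <- adjacency_matrix(B, labs)
  attr(B, "baseline_dates") <- names(first)
  attr(B, "k") <- k
  B
}

#' Weight matrix emphasising transitions
#'
#' Room changes are walked, so they carry more information about mobility
#' than repeated motion inside one room. The weight matrix W up-weights
#' off-diagonal (transition) cells: 1 on the diagonal, 1.5 elsewhere by
#' default. `diag == offdiag == 1` gives the unweighted statistic.
#'
#' @param n Matrix dimension (number of rooms).
#' @param diag Diagonal weight (default 1).
#' @param offdiag Off-diagonal weight (default 1.5).
#' @return An n x n numeric matrix.
#' @export
make_weight_matrix <- function(n, diag = 1, offdiag = 1.5) {
  if (n < 1L) stop("weight matrix dimension must be at least 1")
  if (diag <= 0 || offdiag <= 0) stop("weights must be strictly positive")
  W <- matrix(offdiag, n, n)
  base::diag(W) <- diag
  W
}

#' Weighted baseline-day difference
#'
#' `graph_diff(B, D, W) = sum_ij W_ij * (B_ij - D_ij)`: the total weighted
#' activity mass lost (positive) or gained (negative) on day D relative to
#' the baseline B. Linear in both matrix arguments.
#'
#' @param B Baseline [adjacency_matrix()].
#' @param D Daily [adjacency_matrix()].
#' @param W Weight matrix from [make_weight_matrix()]; default built from
#'   `nrow(B)` with the standard 1 / 1.5 weights.
#' @return A signed scalar.
#' @export
graph_diff <- function(B, D, W = make_weight_matrix(nrow(B))) {
  if (!all(dim(B) == dim(D)) || !all(dim(B) == dim(W)))
    stop("baseline, daily and weight matrices must share one shape")
  if (!is.null(rownames(B)) && !is.null(rownames(D)) &&
      !identical(rownames(B), rownames(D)))
    stop("baseline and daily matrix labels differ")
  sum(W * (unclass(B) - unclass(D)))
}

#' Percent difference of a day from the baseline
#'
#' The day's performance surrogate: the weighted difference as a fraction of
#' the weighted baseline total,
#' `pd = graph_diff(B, D, W) / sum(W * B)`.
#' `pd = 0` means a day exactly like baseline, `pd = 1` total activity loss,
#' negative pd more activity than baseline. Multiply by 100 to report in
#' percent.
#'
#' @inheritParams graph_diff
#' @param date Optional civil date carried through to the result.
#' @return List of class `difference_result` with `raw` (the weighted
#'   difference), `pd` (signed fraction), and `date`.
#' @export
percent_difference <- function(B, D, W = make_weight_matrix(nrow(B)),
                               date = NULL) {
  raw <- graph_diff(B, D, W)
  denom <- sum(W * unclass(B))
  if (denom <= 0)
    stop("degenerate baseline: weighted baseline total is not positive")
  structure(list(raw = raw, pd = raw / denom, date = date),
            class = "difference_result")
}

#' @export
print.difference_result <- function(x, ...) {
  cat("<difference_result>", if (!is.null(x$date)) format(x$date), "raw =",
      format(x$raw), " pd =", sprintf("%.2f%%", 100 * x$pd), "\n")
  invisible(x)
}

#' Per-day percent-difference series
#'
#' Applies [percent_difference()] to every daily matrix. Days that
#' contributed to the baseline are excluded by default so the series
#' measures change relative to, not within, the reference window.
#'
#' @param baseline Baseline matrix from [compute_baseline()].
#' @param dailies Named list (ISO dates) of daily [adjacency_matrix()]
#'   objects; dates must be unique.
#' @param W Weight matrix; default standard 1 / 1.5.
#' @param participant_id Optional id stored on the series.
#' @param exclude_baseline_days Drop the baseline's own dates (default
#'   `TRUE`).
#' @return A data.frame of class `difference_series` with columns `date`
#'   (Date) and `pd` (signed fraction), ordered by date; attributes
#'   `participant_id` and `baseline_dates`.
#' @export
daily_series <- function(baseline, dailies, W = make_weight_matrix(nrow(baseline)),
                         participant_id = NULL,
                         exclude_baseline_days = TRUE) {
  dates <- names(dailies)
  if (is.null(dates) || anyNA(dates))
    stop("dailies must be named by date")
  if (anyDuplicated(dates))
    stop("duplicate dates in daily matrices: ",
         dates[duplicated(dates)][1L])
  bdates <- attr(baseline, "baseline_dates")
  if (exclude_baseline_days && !is.null(bdates)) {
    keep <- !(dates %in% bdates)
    dailies <- dailies[keep]
    dates <- dates[keep]
  }
  pd <- vapply(dailies, function(D)
    percent_difference(baseline, D, W)$pd, numeric(1))
  out <- data.frame(date = as.Date(dates), pd = as.numeric(pd))
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("difference_series", "data.frame"),
            participant_id = participant_id,
            baseline_dates = bdates)
}

#' Write / read a difference series as CSV
#'
#' Header `participant_id,date,pd_percent`; pd is written in percent.
#'
#' @param series A `difference_series` from [daily_series()].
#' @param path CSV path.
#' @name difference_series_io
#' @export
write_difference_series <- function(series, path) {
  pid <- attr(series, "participant_id")
  if (is.null(pid)) pid <- NA_character_
  df <- data.frame(participant_id = pid,
                   date = format(series$date),
                   pd_percent = 100 * series$pd)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname difference_series_io
#' @export
read_difference_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "pd_percent")
  if (!all(need %in% names(df)))
    stop("difference series must have columns: ",
         paste(need, collapse = ", "))
  out <- data.frame(date = as.Date(df$date), pd = df$pd_percent / 100)
  structure(out, class = c("difference_series", "data.frame"),
            participant_id = unique(df$participant_id)[1L])
}
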