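#' Least-squares linear trend of a dated series
#'
#' Fits value = a * day + b by ordinary least squares, the summary used for
#' both the activity (percent-difference) series and the assessment series.
#' The abscissa is days since the series start (0-based), so `a` is change
#' per day in the series' units.
#'
#' @param x Either a data.frame with columns `date` (Date) and a value
#'   column (`pd` or `value`), or a numeric vector of abscissae when `y` is
#'   given.
#' @param y Numeric values when `x` is a numeric abscissa vector.
#' @return Object of class `trend_fit`: list with slope `a`, intercept `b`,
#'   `n_points`, `rss`, and the abscissa origin `t0` (first date, if dated).
#' @export
fit_linear_trend <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(is.data.frame(x))
    vcol <- intersect(c("pd", "value"), names(x))[1L]
    if (is.na(vcol)) stop("no value column ('pd' or 'value') found")
    t0 <- min(x$date)
    t <- as.numeric(x$date - t0)
    y <- x[[vcol]]
  } else {
    t <- as.numeric(x)
    t0 <- NULL
  }
  ok <- !is.na(t) & !is.na(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2L || length(unique(t)) < 2L)
    stop("trend fit needs at least 2 points with distinct abscissae")
  fit <- stats::lm.fit(cbind(intercept = 1, day = t), y)
  structure(list(a = unname(fit$coefficients["day"]),
                 b = unname(fit$coefficients["intercept"]),
                 n_points = length(t),
                 rss = sum(fit$residuals^2),
                 t0 = t0),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> slope a =", format(x$a), "per day, intercept b =",
      format(x$b), " (n =", x$n_points, ")\n")
  invisible(x)
}

#' Evaluate a trend fit
#'
#' @param object A `trend_fit`.
#' @param newdata Numeric day indices.
#' @param ... Unused.
#' @return Fitted values `a * newdata + b`.
#' @export
predict.trend_fit <- function(object, newdata, ...) {
  object$a * as.numeric(newdata) + object$b
}

#' Fitted change over a window
#'
#' The trend's total change across `window` days, `a * window`: the figure
#' quoted when a group is said to have improved or declined by so many
#' points, seconds, or percent over the study.
#'
#' @param fit A `trend_fit`.
#' @param window Window length in days (> 0).
#' @return Scalar change in the series' units.
#' @export
fitted_change <- function(fit, window) {
  stopifnot(inherits(fit, "trend_fit"), window > 0)
  fit$a * window
}

#' Per-group pooled trend with fitted daily values
#'
#' Pools every participant's (day index, value) points within a group into a
#' single least-squares fit (each observed day contributes one point, so
#' participants with more days weigh more), then evaluates both group lines
#' on the common day window \[0, L) where L is the shortest participant
#' span. `method = "average"` instead fits each participant separately and
#' averages the per-participant slopes and intercepts.
#'
#' @param series_list Named list of per-participant `difference_series` (or
#'   data.frames with `date` and a value column).
#' @param groups Named character vector or list mapping participant id to
#'   `"intervention"` / `"control"` (any two labels work).
#' @param method `"pooled"` (default) or `"average"`.
#' @param window Length of the common evaluation window in days; default the
#'   minimum participant span across all groups.
#' @return List of class `group_trend`: per-group `fit` (`trend_fit`),
#'   `fitted` (values on days `0:(window-1)`), plus `window` and `days`.
#' @export
group_trend <- function(series_list, groups, method = c("pooled", "average"),
                        window = NULL) {
  method <- match.arg(method)
  groups <- unlist(groups)
  ids <- names(series_list)
  if (is.null(ids) || !all(ids %in% names(groups)))
    stop("every series needs a group assignment by participant id")
  pts <- lapply(series_list, function(s) {
    vcol <- intersect(c("pd", "value"), names(s))[1L]
    t <- as.numeric(s$date - min(s$date))
    data.frame(t = t, y = s[[vcol]])
  })
  spans <- vapply(pts, function(p) max(p$t) + 1, numeric(1))
  if (is.null(window)) window <- min(spans)
  if (window < 2) stop("common window too short for a trend")
  days <- seq(0, window - 1)
  out <- list()
  for (g in unique(groups[ids])) {
    members <- ids[groups[ids] == g]
    if (!length(members)) stop("empty group: ", g)
    if (method == "pooled") {
      all_pts <- do.call(rbind, pts[members])
      fit <- fit_linear_trend(all_pts$t, all_pts$y)
    } else {
      fits <- lapply(pts[members], function(p) fit_linear_trend(p$t, p$y))
      fit <- structure(list(a = mean(vapply(fits, `[[`, numeric(1), "a")),
                            b = mean(vapply(fits, `[[`, numeric(1), "b")),
                            n_points = sum(vapply(fits, `[[`, numeric(1),
                                                  "n_points")),
                            rss = NA_real_, t0 = NULL),
                       class = "trend_fit")
    }
    out[[g]] <- list(fit = fit, fitted = predict(fit, days),
                     n_participants = length(members))
  }
  structure(list(groups = out, window = window, days = days,
                 method = method),
            class = "group_trend")
}

#' @export
print.group_trend <- function(x, ...) {
  cat("<group_trend> window:", x$window, "days;", x$method, "fit\n")
  for (g in names(x$groups)) {
    f <- x$groups[[g]]$fit
    cat(sprintf("  %-14s slope %+.6g/day, change over window %+.4g (n=%d)\n",
                g, f$a, f$a * x$window, x$groups[[g]]$n_participants))
  }
  invisible(x)
}

#' Paired signed-rank comparison of two fitted daily series
#'
#' Wilcoxon signed-rank test on the day-paired differences of two series of
#' equal length (typically the two groups' fitted activity values over the
#' common window). Zero differences are dropped; ties in |difference| get
#' average ranks; for n > 25 the normal approximation with tie correction
#' and 0.5 continuity correction is used. W is the rank sum of the positive
#' differences.
#'
#' @param fittedA,fittedB Numeric vectors of equal length, paired by day.
#' @param exact_below Use the exact null distribution when the number of
#'   nonzero differences is at most this (default 25) and there are no ties.
#' @return List of class `group_comparison`: `W`, `z`, `p_value`, `n_pairs`
#'   (nonzero pairs), and `degenerate` (`TRUE` when all differences are 0;
#'   then p = 1 by convention).
#' @export
compare_group_fits <- function(fittedA, fittedB, exact_below = 25) {
  if (length(fittedA) != length(fittedB))
    stop("paired comparison needs equal lengths")
  d <- fittedA - fittedB
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(W = 0, z = 0, p_value = 1, n_pairs = 0,
                          degenerate = TRUE), class = "group_comparison"))
  r <- rank(abs(d))  # average ranks on ties
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  has_ties <- any(ties > 1)
  if (n <= exact_below && !has_ties) {
    p_lo <- stats::psignrank(W, n)
    p_hi <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    z <- (W - mu) / sqrt(sigma2)
  } else {
    cc <- 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(W = W, z = z, p_value = min(1, p), n_pairs = n,
                 degenerate = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("<group_comparison> degenerate: all paired differences zero (p = 1)\n")
  } else {
    cat(sprintf("<group_comparison> W = %g, z = %.3f, p = %.3g, n = %d\n",
                x$W, x$z, x$p_value, x$n_pairs))
  }
  invisible(x)
}

#' Relative assessment series
#'
#' Expresses a participant's SPPB or TUG values relative to the first
#' (baseline) assessment: value - first value. Orientation is preserved:
#' positive relative SPPB is improvement, negative relative TUG (shorter
#' time) is improvement.
#'
#' @param assessments data.frame as from [read_assessments()], one
#'   participant.
#' @param metric `"sppb"` or `"tug"`.
#' @return data.frame of class `relative_series` with `date` and `value`
#'   (relative), first value 0; attribute `metric`.
#' @export
relative_series <- function(assessments, metric = c("sppb", "tug")) {
  metric <- match.arg(metric)
  if (nrow(assessments) < 1L) stop("need at least one assessment record")
  a <- assessments[order(assessments$date), , drop = FALSE]
  v <- a[[metric]]
  out <- data.frame(date = a$date, value = v - v[1L])
  rownames(out) <- NULL
  structure(out, class = c("relative_series", "data.frame"),
            metric = metric,
            participant_id = unique(a$participant_id)[1L])
}
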