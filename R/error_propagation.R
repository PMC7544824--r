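# Propagation of multiplicative fluorescence-ratio errors into value space.
#
# The empirical error model is R_Obs = R_True * (1 + eps), with eps a
# zero-median multiplicative error whose central-coverage quantiles define a
# relative-error interval. Because every calibration map here is monotone in
# R, the coverage interval of the observed value is obtained by propagating
# the two interval endpoints through the map -- no sampling needed.

#' Relative-error interval of fluorescence-ratio measurements
#'
#' Central-coverage bounds on the multiplicative error `eps` in
#' `R_Obs = R_True * (1 + eps)`. A single non-negative argument builds a
#' symmetric interval, e.g. `error_interval(0.028)` for the +/-2.8% interval.
#'
#' @param lower Lower quantile of `eps` (<= 0), or, when `upper` is missing
#'   and `lower >= 0`, the half-width of a symmetric interval.
#' @param upper Upper quantile of `eps` (>= 0).
#' @param coverage Probability mass between the bounds, default 0.95.
#' @return An object of class `"error_interval"`.
#' @examples
#' error_interval(0.028)            # symmetric +/-2.8%
#' error_interval(-0.02, 0.035)     # asymmetric
#' @export
error_interval <- function(lower, upper = NULL, coverage = 0.95) {
  if (is.null(upper)) {
    if (lower < 0) stop("symmetric shorthand requires a non-negative half-width", call. = FALSE)
    upper <- lower; lower <- -lower
  }
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1, length(upper) == 1)
  if (!(lower <= 0 && upper >= 0)) stop("error interval must satisfy lower <= 0 <= upper", call. = FALSE)
  if (lower <= -1) stop("lower must exceed -1 (a ratio cannot lose more than all of itself)", call. = FALSE)
  if (!(coverage > 0 && coverage < 1)) stop("coverage must lie in (0, 1)", call. = FALSE)
  structure(list(lower = lower, upper = upper, coverage = coverage),
            class = "error_interval")
}

#' @export
print.error_interval <- function(x, ...) {
  cat(sprintf("Relative error in R: (%+.4g%%, %+.4g%%) at %g%% coverage\n",
              100 * x$lower, 100 * x$upper, 100 * x$coverage))
  invisible(x)
}

.as_error <- function(err) {
  if (inherits(err, "error_interval")) return(err)
  if (is.numeric(err) && length(err) == 1) return(error_interval(err))
  if (is.numeric(err) && length(err) == 2) return(error_interval(err[1], err[2]))
  stop("expected an 'error_interval', a half-width, or a (lower, upper) pair", call. = FALSE)
}

# weighted quantile of (x, w) by linear interpolation of the weighted
# empirical CDF evaluated at the midpoints of the weight increments
.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  # CDF knots at midpoints of each step; reduces bias at small n
  knots <- cw - w / (2 * sum(w))
  stats::approx(knots, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Aggregate per-experiment fold errors into a relative-error interval
#'
#' Each experiment contributes total weight `1/k` regardless of how many
#' error observations it holds (equal-weight aggregation across `k`
#' experiments), and the interval is the pair of central-coverage weighted
#' quantiles of the pooled distribution.
#'
#' @param errors_by_experiment List of numeric vectors of fold errors
#'   (`eps` values), one vector per experiment, each with at least 2 entries.
#' @param coverage Central coverage, default 0.95.
#' @return An [error_interval()].
#' @examples
#' set.seed(1)
#' empirical_error_interval(list(rnorm(1e4, 0, 0.014)))
#' @export
empirical_error_interval <- function(errors_by_experiment, coverage = 0.95) {
  if (!is.list(errors_by_experiment) || length(errors_by_experiment) == 0)
    stop("provide a non-empty list of per-experiment fold-error vectors", call. = FALSE)
  sizes <- vapply(errors_by_experiment, length, integer(1))
  if (any(sizes < 2)) stop("each experiment needs at least 2 fold errors", call. = FALSE)
  k <- length(errors_by_experiment)
  x <- unlist(errors_by_experiment, use.names = FALSE)
  if (any(!is.finite(x))) stop("fold errors must be finite", call. = FALSE)
  w <- unlist(lapply(sizes, function(n) rep(1 / (k * n), n)), use.names = FALSE)
  a <- (1 - coverage) / 2
  q <- .weighted_quantile(x, w, c(a, 1 - a))
  # an interval not bracketing zero means the errors are not zero-median;
  # widen to include zero so that the no-error identity still holds
  error_interval(min(q[1], 0), max(q[2], 0), coverage = coverage)
}

#' Coverage bounds of the observed value at a given true value
#'
#' Propagates the endpoints of the relative-error interval through the
#' (monotone) calibration map: with `R_True = ratio_from_value(value_true)`,
#' the bounds are the sorted pair of values at `R_True * (1 + lower)` and
#' `R_True * (1 + upper)`. A perturbed ratio that exits the sensor gamut
#' yields an infinite bound (that side of the value axis is unbounded).
#'
#' @param value_true True biochemical value(s).
#' @param sensor A [biosensor()].
#' @param err An [error_interval()] (or half-width shorthand).
#' @return For scalar input a sorted length-2 vector `(value_lo, value_hi)`;
#'   for vector input a 2-column matrix.
#' @export
observed_bounds <- function(value_true, sensor, err) {
  stopifnot(inherits(sensor, "biosensor"))
  err <- .as_error(err)
  R_true <- ratio_from_value(value_true, sensor)
  v1 <- .value_from_ratio_ext(R_true * (1 + err$lower), sensor)
  v2 <- .value_from_ratio_ext(R_true * (1 + err$upper), sensor)
  lo <- pmin(v1, v2); hi <- pmax(v1, v2)
  if (length(value_true) == 1L) c(lo, hi) else cbind(value_lo = lo, value_hi = hi)
}

#' Predicted measurement inaccuracy at a true value
#'
#' The maximum absolute difference between the true value and either
#' coverage bound of the observed value; `+Inf` where a perturbed ratio
#' exits the sensor gamut (impossible to measure accurately).
#'
#' @inheritParams observed_bounds
#' @return Non-negative inaccuracy (same units as the value), possibly `Inf`.
#' @export
inaccuracy <- function(value_true, sensor, err) {
  stopifnot(inherits(sensor, "biosensor"))
  err <- .as_error(err)
  R_true <- ratio_from_value(value_true, sensor)
  v1 <- .value_from_ratio_ext(R_true * (1 + err$lower), sensor)
  v2 <- .value_from_ratio_ext(R_true * (1 + err$upper), sensor)
  pmax(abs(value_true - v1), abs(value_true - v2))
}

#' Inaccuracy as a function of the true value
#'
#' Evaluates [inaccuracy()] over a grid of true values.
#'
#' @inheritParams observed_bounds
#' @param grid Numeric vector of true values; defaults to [value_grid()] for
#'   the sensor's kind.
#' @return An object of class `"inaccuracy_curve"`: a list with `values`,
#'   `inaccuracy`, `sensor` (name), `kind`, and `error`.
#' @examples
#' s <- biosensor("demo", "redox", R_A = 1, R_B = 5, delta2 = 0.2, e0 = -265)
#' curve <- inaccuracy_curve(s, error_interval(0.028))
#' summary(curve)
#' @export
inaccuracy_curve <- function(sensor, err, grid = value_grid(sensor)) {
  stopifnot(inherits(sensor, "biosensor"))
  err <- .as_error(err)
  structure(list(values = grid,
                 inaccuracy = inaccuracy(grid, sensor, err),
                 sensor = sensor$name, kind = sensor$kind, error = err),
            class = "inaccuracy_curve")
}

#' @export
as.data.frame.inaccuracy_curve <- function(x, ...) {
  data.frame(value = x$values, inaccuracy = x$inaccuracy)
}

#' @export
print.inaccuracy_curve <- function(x, ...) {
  cat(sprintf("<inaccuracy_curve> sensor %s [%s], %d grid points\n",
              x$sensor, x$kind, length(x$values)))
  print(x$error)
  invisible(x)
}

#' @export
summary.inaccuracy_curve <- function(object, ...) {
  fin <- is.finite(object$inaccuracy)
  i <- which.min(replace(object$inaccuracy, !fin, Inf))
  cat(sprintf("Inaccuracy curve for %s [%s]\n", object$sensor, object$kind))
  cat(sprintf("  finite on %d of %d grid points\n", sum(fin), length(fin)))
  if (any(fin))
    cat(sprintf("  minimum inaccuracy %.4g %s at value %.4g\n",
                object$inaccuracy[i], .value_unit(object$kind), object$values[i]))
  invisible(object)
}

#' @export
plot.inaccuracy_curve <- function(x, ylim = NULL, ...) {
  y <- x$inaccuracy
  fin <- is.finite(y)
  if (is.null(ylim)) ylim <- c(0, min(max(y[fin]), 20 * min(y[fin])))
  graphics::plot(x$values, replace(y, !fin, NA), type = "l",
                 xlab = sprintf("true value (%s)", .value_unit(x$kind)),
                 ylab = sprintf("predicted inaccuracy (%s)", .value_unit(x$kind)),
                 main = x$sensor, ylim = ylim, ...)
  invisible(x)
}

# contiguous runs of TRUE in a logical vector -> 2-column index matrix
.true_runs <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# bisection for inaccuracy(value) == threshold between a sub-threshold and a
# super-threshold value; returns the boundary to tolerance tol
.bisect_edge <- function(sensor, err, threshold, inside, outside, tol = 1e-3) {
  for (i in seq_len(80)) {
    mid <- (inside + outside) / 2
    if (abs(outside - inside) < tol) break
    if (inaccuracy(mid, sensor, err) - threshold <= 0) inside <- mid else outside <- mid
  }
  (inside + outside) / 2
}

#' Range of values measurable within a stated inaccuracy
#'
#' Finds the interval of true values whose predicted [inaccuracy()] is at or
#' below `threshold`: a coarse grid scan locates the sub-threshold region,
#' then bisection refines both endpoints to `tol` value units. With a
#' monotone calibration map the inaccuracy curve is quasiconvex, so the
#' region is a single interval; sub-threshold islands separated by fewer
#' than 2 grid steps (floating-point artifacts) are merged with a warning,
#' and if genuinely separate islands remain, the one containing the curve
#' minimum is kept (with a warning).
#'
#' @inheritParams inaccuracy_curve
#' @param threshold Maximum tolerated inaccuracy (> 0), in value units.
#' @param tol Endpoint refinement tolerance, default 1e-3 value units.
#' @return An object of class `"suitable_range"`: `threshold`, `interval`
#'   (length-2 numeric, or `NULL` if empty), `sensor`, `kind`, `error`.
#' @examples
#' s <- biosensor("demo", "redox", R_A = 1, R_B = 5, delta2 = 0.2, e0 = -265)
#' suitable_range(s, error_interval(0.028), threshold = 2)
#' @export
suitable_range <- function(sensor, err, threshold, grid = value_grid(sensor), tol = 1e-3) {
  stopifnot(inherits(sensor, "biosensor"))
  err <- .as_error(err)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number", call. = FALSE)
  ia <- inaccuracy(grid, sensor, err)
  ok <- is.finite(ia) & ia <= threshold
  empty <- structure(list(threshold = threshold, interval = NULL,
                          sensor = sensor$name, kind = sensor$kind, error = err),
                     class = "suitable_range")
  if (!any(ok)) return(empty)
  runs <- .true_runs(ok)
  if (nrow(runs) > 1) {
    # merge islands separated by < 2 grid steps
    merged <- runs[1, , drop = FALSE]
    for (i in seq_len(nrow(runs) - 1L) + 1L) {
      if (runs[i, "start"] - merged[nrow(merged), "end"] < 2L) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
        warning("merged sub-threshold islands separated by < 2 grid steps", call. = FALSE)
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
    if (nrow(runs) > 1) {
      warning("discontiguous sub-threshold regions; keeping the one containing the curve minimum",
              call. = FALSE)
      imin <- which.min(replace(ia, !is.finite(ia), Inf))
      keep <- which(runs[, "start"] <= imin & imin <= runs[, "end"])
      if (length(keep) == 0) keep <- which.max(runs[, "end"] - runs[, "start"])
      runs <- runs[keep[1], , drop = FALSE]
    }
  }
  i0 <- runs[1, "start"]; i1 <- runs[1, "end"]
  lo <- if (i0 > 1L) .bisect_edge(sensor, err, threshold, grid[i0], grid[i0 - 1L], tol) else grid[1L]
  hi <- if (i1 < length(grid)) .bisect_edge(sensor, err, threshold, grid[i1], grid[i1 + 1L], tol) else grid[length(grid)]
  structure(list(threshold = threshold, interval = c(lo, hi),
                 sensor = sensor$name, kind = sensor$kind, error = err),
            class = "suitable_range")
}

#' @export
print.suitable_range <- function(x, ...) {
  if (is.null(x$interval)) {
    cat(sprintf("Suitable range for %s at <= %g %s: empty\n",
                x$sensor, x$threshold, .value_unit(x$kind)))
  } else {
    p <- .present_value(x$interval, x$kind)
    cat(sprintf("Suitable range for %s at <= %g %s: [%g, %g]\n",
                x$sensor, x$threshold, .value_unit(x$kind), p[1], p[2]))
  }
  invisible(x)
}

#' @export
as.data.frame.suitable_range <- function(x, ...) {
  if (is.null(x$interval))
    data.frame(sensor = x$sensor, threshold = x$threshold,
               lower = NA_real_, upper = NA_real_)
  else
    data.frame(sensor = x$sensor, threshold = x$threshold,
               lower = x$interval[1], upper = x$interval[2])
}

#' Serialize a curve or range to CSV or JSON
#'
#' Curves write two columns (`value`, `inaccuracy`); ranges write one row
#' (`sensor`, `threshold`, `lower`, `upper`). Values are written at double
#' precision (they round-trip losslessly).
#'
#' @param x An `"inaccuracy_curve"` or `"suitable_range"` (or any object with
#'   an `as.data.frame` method).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_table <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "csv") {
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, na = "null")
  }
  invisible(path)
}
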