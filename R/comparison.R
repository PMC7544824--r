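# Comparison of sensors of a common kind: best-sensor envelope, optimal
# windows, coverage gaps, and measurement-feasibility phase diagrams.

# ties in the pointwise argmin closer than this (value units) go to the
# earlier sensor in the input list
.TIE_TOL <- 1e-9

.check_sensor_list <- function(sensors) {
  if (inherits(sensors, "biosensor")) sensors <- list(sensors)
  if (!is.list(sensors) || length(sensors) == 0 ||
      !all(vapply(sensors, inherits, logical(1), "biosensor")))
    stop("expected a non-empty list of biosensor objects", call. = FALSE)
  kinds <- unique(vapply(sensors, function(s) s$kind, character(1)))
  if (length(kinds) != 1)
    stop("all sensors must be of the same kind; got: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  sensors
}

# resolve a shared error interval or a per-sensor named mapping into a list
# parallel to `sensors` (filter choice can change measurement precision, so
# per-sensor intervals are allowed)
.errors_for <- function(sensors, err) {
  if (is.list(err) && !inherits(err, "error_interval")) {
    nm <- vapply(sensors, function(s) s$name, character(1))
    if (is.null(names(err)) || !all(nm %in% names(err)))
      stop("per-sensor error mapping must name every sensor", call. = FALSE)
    lapply(nm, function(n) .as_error(err[[n]]))
  } else {
    rep(list(.as_error(err)), length(sensors))
  }
}

# grid x sensor matrix of inaccuracies
.inaccuracy_matrix <- function(sensors, errs, grid) {
  m <- vapply(seq_along(sensors),
              function(i) inaccuracy(grid, sensors[[i]], errs[[i]]),
              numeric(length(grid)))
  matrix(m, nrow = length(grid))  # keep matrix shape for length-1 grids
}

# first index attaining the row minimum within .TIE_TOL; NA if all infinite
.argmin_rows <- function(m) {
  env <- do.call(pmin, as.data.frame(m))
  idx <- rep(NA_integer_, nrow(m))
  fin <- is.finite(env)
  if (any(fin)) {
    hit <- m[fin, , drop = FALSE] <= env[fin] + .TIE_TOL
    idx[fin] <- apply(hit, 1L, which.max)  # first TRUE = earliest sensor
  }
  list(envelope = env, idx = idx)
}

#' Pointwise most-accurate sensor across a value grid
#'
#' For each grid value, the sensor with the smallest predicted
#' [inaccuracy()] (the lower envelope of all inaccuracy curves). Ties within
#' 1e-9 value units go to the earlier sensor in the input list.
#'
#' @param sensors List of [biosensor()] objects, all of the same kind.
#' @param err Shared [error_interval()] (or half-width), or a named list
#'   mapping each sensor name to its own interval.
#' @param grid Value grid; defaults to [value_grid()] for the sensors' kind.
#' @return An object of class `"best_sensor_curve"`: `values`, `envelope`
#'   (pointwise minimum inaccuracy), `sensor` (winning name per point, `NA`
#'   where all sensors are infinitely inaccurate), `kind`, `sensors` (input
#'   names), `error`.
#' @export
best_sensor_curve <- function(sensors, err, grid = NULL) {
  sensors <- .check_sensor_list(sensors)
  if (is.null(grid)) grid <- value_grid(sensors[[1]])
  errs <- .errors_for(sensors, err)
  m <- .inaccuracy_matrix(sensors, errs, grid)
  am <- .argmin_rows(m)
  nm <- vapply(sensors, function(s) s$name, character(1))
  structure(list(values = grid, envelope = am$envelope,
                 sensor = ifelse(is.na(am$idx), NA_character_, nm[am$idx]),
                 kind = sensors[[1]]$kind, sensors = nm, error = err),
            class = "best_sensor_curve")
}

#' @export
as.data.frame.best_sensor_curve <- function(x, ...) {
  data.frame(value = x$values, inaccuracy = x$envelope, sensor = x$sensor)
}

#' @export
print.best_sensor_curve <- function(x, ...) {
  cat(sprintf("<best_sensor_curve> %d sensors [%s], %d grid points\n",
              length(x$sensors), x$kind, length(x$values)))
  tab <- table(x$sensor)
  if (length(tab)) {
    cat("  winners:\n")
    for (n in names(tab))
      cat(sprintf("    %s: %d points\n", n, tab[[n]]))
  }
  invisible(x)
}

#' @export
plot.best_sensor_curve <- function(x, ...) {
  fin <- is.finite(x$envelope)
  graphics::plot(x$values, replace(x$envelope, !fin, NA), type = "l",
                 xlab = sprintf("true value (%s)", .value_unit(x$kind)),
                 ylab = sprintf("envelope inaccuracy (%s)", .value_unit(x$kind)), ...)
  invisible(x)
}

#' Value windows where each sensor is the most accurate
#'
#' Partitions the finite-envelope portion of the grid into maximal runs won
#' by a single sensor; boundaries are reported at grid resolution.
#'
#' @inheritParams best_sensor_curve
#' @return Named list (one entry per sensor that wins somewhere) of 2-column
#'   matrices of window `[lower, upper]` value bounds.
#' @export
optimal_windows <- function(sensors, err, grid = NULL) {
  bc <- best_sensor_curve(sensors, err, grid)
  wins <- bc$sensor
  out <- stats::setNames(vector("list", length(bc$sensors)), bc$sensors)
  if (all(is.na(wins))) return(out[lengths(out) > 0])
  r <- rle(wins)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    nm <- r$values[j]
    if (is.na(nm)) next
    out[[nm]] <- rbind(out[[nm]], c(bc$values[starts[j]], bc$values[ends[j]]))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  lapply(out, function(m) { colnames(m) <- c("lower", "upper"); m })
}

#' Value intervals no sensor can measure within a threshold
#'
#' The complement, within the grid bounds, of the union of the sensors'
#' suitable ranges: intervals where the best-sensor envelope exceeds
#' `threshold`.
#'
#' @inheritParams best_sensor_curve
#' @param threshold Maximum tolerated inaccuracy (> 0).
#' @return 2-column matrix of gap `[lower, upper]` bounds (0 rows if none).
#' @export
coverage_gaps <- function(sensors, err, threshold, grid = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive number", call. = FALSE)
  bc <- best_sensor_curve(sensors, err, grid)
  bad <- !(bc$envelope <= threshold)
  out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lower", "upper")))
  if (!any(bad)) return(out)
  runs <- .true_runs(bad)
  cbind(lower = bc$values[runs[, "start"]], upper = bc$values[runs[, "end"]])
}

#' Measurement-feasibility phase diagram
#'
#' Classifies each (true value, tolerated inaccuracy) pair as feasible
#' (predicted inaccuracy at or below the tolerance) or not. The feasibility
#' boundary, read as a function of the value, is the inaccuracy curve (or
#' best-sensor envelope) itself. A maximum tolerable inaccuracy line
#' separates scientifically useful tolerances from useless ones.
#'
#' @param x A [biosensor()], a list of them (the envelope is used), or an
#'   `"inaccuracy_curve"` / `"best_sensor_curve"` object.
#' @param err Error interval (ignored when `x` is already a curve).
#' @param grid Value grid (ignored when `x` is already a curve).
#' @param thresholds Grid of tolerated-inaccuracy levels (value units).
#' @param max_tolerable Optional maximum tolerable inaccuracy for plotting.
#' @return An object of class `"phase_diagram"`: `values`, `thresholds`,
#'   `feasible` (values x thresholds logical matrix), `boundary` (minimal
#'   feasible tolerance per value = the inaccuracy curve), `max_tolerable`,
#'   `kind`.
#' @export
phase_diagram <- function(x, err = NULL, grid = NULL,
                          thresholds = NULL, max_tolerable = NULL) {
  if (inherits(x, "biosensor")) {
    if (is.null(grid)) grid <- value_grid(x)
    boundary <- inaccuracy(grid, x, .as_error(err))
    kind <- x$kind
  } else if (inherits(x, "inaccuracy_curve") || inherits(x, "best_sensor_curve")) {
    grid <- x$values
    boundary <- if (inherits(x, "inaccuracy_curve")) x$inaccuracy else x$envelope
    kind <- x$kind
  } else {
    bc <- best_sensor_curve(x, err, grid)
    grid <- bc$values; boundary <- bc$envelope; kind <- bc$kind
  }
  if (is.null(thresholds)) {
    fin <- boundary[is.finite(boundary)]
    top <- if (length(fin)) stats::quantile(fin, 0.9, names = FALSE) else 1
    thresholds <- seq(0, max(top, if (is.null(max_tolerable)) 0 else 2 * max_tolerable),
                      length.out = 201)[-1]
  }
  feas <- outer(boundary, thresholds, `<=`)
  feas[!is.finite(boundary), ] <- FALSE
  dimnames(feas) <- NULL
  structure(list(values = grid, thresholds = thresholds, feasible = feas,
                 boundary = boundary, max_tolerable = max_tolerable, kind = kind),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d values x %d tolerance levels [%s]; %.1f%% feasible\n",
              length(x$values), length(x$thresholds), x$kind,
              100 * mean(x$feasible)))
  invisible(x)
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  data.frame(value = rep(x$values, times = length(x$thresholds)),
             threshold = rep(x$thresholds, each = length(x$values)),
             feasible = as.vector(x$feasible))
}

#' @param x A `"phase_diagram"`.
#' @param ... Passed to [graphics::image()].
#' @rdname phase_diagram
#' @export
plot.phase_diagram <- function(x, ...) {
  # regions: green = feasible & tolerable; orange = feasible but beyond the
  # tolerable line; light red = tolerable but infeasible; red = neither
  mt <- if (is.null(x$max_tolerable)) max(x$thresholds) else x$max_tolerable
  tolerable <- matrix(rep(x$thresholds <= mt, each = length(x$values)),
                      nrow = length(x$values))
  z <- matrix(1L, nrow = length(x$values), ncol = length(x$thresholds))
  z[x$feasible & tolerable] <- 4L
  z[x$feasible & !tolerable] <- 3L
  z[!x$feasible & tolerable] <- 2L
  cols <- c("#d7301f", "#fcae91", "#fd8d3c", "#31a354")
  graphics::image(x$values, x$thresholds, z, zlim = c(1, 4), col = cols,
                  xlab = sprintf("true value (%s)", .value_unit(x$kind)),
                  ylab = sprintf("tolerated inaccuracy (%s)", .value_unit(x$kind)),
                  useRaster = TRUE, ...)
  graphics::lines(x$values, replace(x$boundary, !is.finite(x$boundary), NA), lwd = 1.5)
  if (!is.null(x$max_tolerable))
    graphics::abline(h = x$max_tolerable, lty = 2)
  invisible(x)
}
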