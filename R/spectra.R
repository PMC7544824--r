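# Two-state excitation/emission spectra, band integration, derivation of
# conversion factors from spectra, and exhaustive optimal filter-band search.

#' Two-state fluorescence spectrum
#'
#' Tabulated per-wavelength intensities of the pure state-A and state-B
#' ensembles, on a shared strictly increasing wavelength axis.
#'
#' @param wavelengths Wavelengths in nm, strictly increasing, length >= 2.
#' @param intensity_A,intensity_B Non-negative intensities (arbitrary units),
#'   same length as `wavelengths`.
#' @param axis `"excitation"` or `"emission"`.
#' @return An object of class `"two_state_spectrum"`.
#' @export
two_state_spectrum <- function(wavelengths, intensity_A, intensity_B,
                               axis = c("excitation", "emission")) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(wavelengths), is.numeric(intensity_A), is.numeric(intensity_B))
  if (length(wavelengths) < 2) stop("a spectrum needs at least 2 wavelength points", call. = FALSE)
  if (length(intensity_A) != length(wavelengths) || length(intensity_B) != length(wavelengths))
    stop("intensity vectors must match the wavelength vector in length", call. = FALSE)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(intensity_A < 0) || any(intensity_B < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(list(wavelengths = wavelengths, intensity_A = intensity_A,
                 intensity_B = intensity_B, axis = axis),
            class = "two_state_spectrum")
}

#' @export
print.two_state_spectrum <- function(x, ...) {
  cat(sprintf("<two_state_spectrum> %s axis, %d points, %g-%g nm\n",
              x$axis, length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
plot.two_state_spectrum <- function(x, ...) {
  graphics::matplot(x$wavelengths, cbind(x$intensity_A, x$intensity_B),
                    type = "l", lty = 1, col = c("#1b9e77", "#d95f02"),
                    xlab = "wavelength (nm)", ylab = "intensity (a.u.)",
                    main = paste(x$axis, "spectrum"), ...)
  graphics::legend("topright", legend = c("state A", "state B"),
                   col = c("#1b9e77", "#d95f02"), lty = 1, bty = "n")
  invisible(x)
}

#' Wavelength band
#'
#' A contiguous wavelength interval over which fluorescence is collected
#' (an idealized filter).
#'
#' @param low,high Band edges in nm, `low < high`.
#' @return An object of class `"wavelength_band"`.
#' @export
wavelength_band <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1, length(high) == 1)
  if (!(low < high)) stop("band requires low < high", call. = FALSE)
  structure(list(low = low, high = high), class = "wavelength_band")
}

.as_band <- function(b) {
  if (inherits(b, "wavelength_band")) return(b)
  if (is.numeric(b) && length(b) == 2) return(wavelength_band(b[1], b[2]))
  stop("expected a wavelength_band or a (low, high) pair", call. = FALSE)
}

#' @export
print.wavelength_band <- function(x, ...) {
  cat(sprintf("<wavelength_band> %g-%g nm\n", x$low, x$high))
  invisible(x)
}

#' Integrated intensity of one state over a band
#'
#' Trapezoidal integral of the tabulated intensity over the band, with
#' linear interpolation at the band edges. Additive over band partitions.
#' Spectra are typically tabulated at about 1 nm; higher-order quadrature
#' would be spurious precision.
#'
#' @param spectrum A [two_state_spectrum()].
#' @param state `"A"` or `"B"`.
#' @param band A [wavelength_band()] or `(low, high)` pair; must intersect
#'   the spectrum support.
#' @return Integrated intensity (a.u. x nm), non-negative.
#' @export
band_intensity <- function(spectrum, state = c("A", "B"), band) {
  stopifnot(inherits(spectrum, "two_state_spectrum"))
  state <- match.arg(state)
  band <- .as_band(band)
  wl <- spectrum$wavelengths
  y <- if (state == "A") spectrum$intensity_A else spectrum$intensity_B
  lo <- max(band$low, wl[1]); hi <- min(band$high, wl[length(wl)])
  if (!(lo < hi))
    stop(sprintf("band %g-%g nm does not overlap the spectrum support %g-%g nm",
                 band$low, band$high, wl[1], wl[length(wl)]), call. = FALSE)
  inner <- wl[wl > lo & wl < hi]
  xs <- c(lo, inner, hi)
  ys <- stats::approx(wl, y, xout = xs, ties = "ordered")$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Conversion factors implied by a spectrum and two bands
#'
#' With band intensities `I_s(b)` (state `s`, band `b`):
#' `R_A = I_A(band1)/I_A(band2)`, `R_B = I_B(band1)/I_B(band2)`,
#' `delta2 = I_B(band2)/I_A(band2)`. All three are invariant to rescaling
#' both states by a common factor.
#'
#' @inheritParams band_intensity
#' @param band1,band2 The two collection bands.
#' @return A [conversion_factors()] object.
#' @export
factors_from_spectra <- function(spectrum, band1, band2) {
  iA1 <- band_intensity(spectrum, "A", band1)
  iA2 <- band_intensity(spectrum, "A", band2)
  iB1 <- band_intensity(spectrum, "B", band1)
  iB2 <- band_intensity(spectrum, "B", band2)
  if (any(c(iA1, iA2, iB1, iB2) <= 0))
    stop("zero integrated intensity in a band; all four band intensities must be positive",
         call. = FALSE)
  R_A <- iA1 / iA2; R_B <- iB1 / iB2
  if (abs(R_A - R_B) <= 1e-9 * max(R_A, R_B))
    stop("degenerate sensor: the two states give the same ratio in these bands",
         call. = FALSE)
  conversion_factors(R_A, R_B, delta2 = iB2 / iA2)
}

# enumerate contiguous candidate bands on a low-edge/width lattice
.enumerate_bands <- function(wl_min, wl_max, min_width, step, max_width = NULL) {
  if (is.null(max_width)) max_width <- min_width
  widths <- seq(min_width, max_width, by = step)
  out <- list()
  for (w in widths) {
    lows <- seq(wl_min, wl_max - w, by = step)
    for (lo in lows) out[[length(out) + 1L]] <- wavelength_band(lo, lo + w)
  }
  out
}

#' Exhaustive search for the optimal pair of filter bands
#'
#' Enumerates contiguous candidate bands on a regular lattice (low edges and
#' widths in steps of `step` nm), derives the conversion factors of every
#' unordered band pair, and selects the pair maximizing the width of the
#' [suitable_range()] at the stated inaccuracy threshold. Ties are broken by
#' smaller minimum inaccuracy, then by lower `band1` low edge, then by lower
#' `band2` low edge; the result is deterministic. The search couples to a
#' single error interval: the effect of filter choice on the photon budget
#' (and hence on the error itself) is out of scope.
#'
#' @inheritParams band_intensity
#' @param kind Sensor kind (`"redox"`, `"pH"`, `"ligand"`).
#' @param constant Chemistry constant (midpoint potential in mV, pKa or pKd).
#' @param err [error_interval()] or half-width shorthand.
#' @param threshold Inaccuracy threshold defining the objective (value units).
#' @param min_width Minimum band width in nm, default 10.
#' @param step Lattice step in nm, default 5.
#' @param max_width Maximum band width; defaults to `min_width` (fixed-width
#'   bands), raise to enlarge the search space.
#' @param grid Value grid for the suitable-range objective.
#' @param z,temperature Redox chemistry parameters.
#' @return A list of class `"band_optimization"`: `band1`, `band2`, `factors`,
#'   `sensor`, `range` (the winning [suitable_range()]), `objective`
#'   (range width), `min_inaccuracy`, `n_pairs` (pairs evaluated).
#' @export
optimize_bands <- function(spectrum, kind, constant, err, threshold,
                           min_width = 10, step = 5, max_width = NULL,
                           grid = value_grid(kind), z = 2L, temperature = 298.15) {
  stopifnot(inherits(spectrum, "two_state_spectrum"))
  err <- .as_error(err)
  wl <- spectrum$wavelengths
  bands <- .enumerate_bands(wl[1], wl[length(wl)], min_width, step, max_width)
  if (length(bands) < 2) stop("band search space is empty for this spectrum and settings",
                              call. = FALSE)
  best <- NULL
  n_pairs <- 0L
  mk_sensor <- function(fac) {
    switch(kind,
           redox = biosensor("candidate", "redox", factors = fac, e0 = constant,
                             z = z, temperature = temperature),
           pH = biosensor("candidate", "pH", factors = fac, pKa = constant),
           ligand = biosensor("candidate", "ligand", factors = fac, pKd = constant))
  }
  for (i in seq_len(length(bands) - 1L)) {
    for (j in seq(i + 1L, length(bands))) {
      n_pairs <- n_pairs + 1L
      fac <- tryCatch(factors_from_spectra(spectrum, bands[[i]], bands[[j]]),
                      error = function(e) NULL)
      if (is.null(fac)) next
      sensor <- mk_sensor(fac)
      ia <- inaccuracy(grid, sensor, err)
      fin <- is.finite(ia)
      min_ia <- if (any(fin)) min(ia[fin]) else Inf
      sr <- suppressWarnings(suitable_range(sensor, err, threshold, grid = grid))
      width <- if (is.null(sr$interval)) 0 else diff(sr$interval)
      cand <- list(band1 = bands[[i]], band2 = bands[[j]], factors = fac,
                   sensor = sensor, range = sr, objective = width,
                   min_inaccuracy = min_ia)
      if (is.null(best) ||
          width > best$objective + 1e-12 ||
          (abs(width - best$objective) <= 1e-12 && min_ia < best$min_inaccuracy - 1e-12)) {
        best <- cand
      }
    }
  }
  if (is.null(best))
    stop("no band pair yields a non-degenerate sensor", call. = FALSE)
  best$n_pairs <- n_pairs
  class(best) <- "band_optimization"
  best
}

#' @export
print.band_optimization <- function(x, ...) {
  cat(sprintf("<band_optimization> band1 %g-%g nm, band2 %g-%g nm (%d pairs searched)\n",
              x$band1$low, x$band1$high, x$band2$low, x$band2$high, x$n_pairs))
  cat(sprintf("  suitable-range width %.4g; minimum inaccuracy %.4g\n",
              x$objective, x$min_inaccuracy))
  print(x$factors)
  print(x$range)
  invisible(x)
}

#' Read and write two-state spectra as CSV
#'
#' The format is a UTF-8 comma-separated file with header
#' `wavelength_nm,intensity_stateA,intensity_stateB`; lines starting with
#' `#` are comments.
#'
#' @param path File path.
#' @param axis `"excitation"` or `"emission"` (the file does not carry it).
#' @return [two_state_spectrum()] for the reader; `path`, invisibly, for the
#'   writer.
#' @export
read_spectrum_csv <- function(path, axis = c("excitation", "emission")) {
  axis <- match.arg(axis)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "intensity_stateA", "intensity_stateB")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  two_state_spectrum(df$wavelength_nm, df$intensity_stateA, df$intensity_stateB, axis = axis)
}

#' @param spectrum A [two_state_spectrum()].
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "two_state_spectrum"))
  df <- data.frame(wavelength_nm = spectrum$wavelengths,
                   intensity_stateA = spectrum$intensity_A,
                   intensity_stateB = spectrum$intensity_B)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
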