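# Core calibration maps for two-state ratiometric biosensors.
#
# A two-state sensor interconverts between a low-value reference state A
# (reduced / protonated / apo) and a high-value state B (oxidized /
# deprotonated / ligand-bound). The fluorescence ratio R of an ensemble is a
# Moebius function of the fraction of molecules in state B, parameterized by
# three conversion factors: the pure-state ratios R_A and R_B and the
# second-band dynamic range delta2 (state-B over state-A intensity in band 2).

.R_GAS   <- 8.314462618  # J mol^-1 K^-1
.FARADAY <- 96485.33212  # C mol^-1
.FRACTION_CLIP <- 1e-12  # applied only inside logs; raw fraction kept for gamut checks

# Nernst slope in mV: RT/zF * 1000
.nernst_mV <- function(temperature, z) {
  1000 * .R_GAS * temperature / (z * .FARADAY)
}

#' Conversion factors of a two-state ratiometric biosensor
#'
#' The three quantities that map a fluorescence ratio to a state fraction:
#' `R_A`, the ratio of a pure state-A ensemble; `R_B`, the ratio of a pure
#' state-B ensemble; and `delta2`, the state-B over state-A fluorescence
#' intensity in the second (denominator) band. Sensors whose ratio decreases
#' upon activation are represented by `R_B < R_A`; no special casing is
#' needed anywhere downstream.
#'
#' @param R_A,R_B Pure-state fluorescence ratios (band 1 / band 2); positive,
#'   distinct.
#' @param delta2 Second-band dynamic range, positive.
#' @return An object of class `"conversion_factors"` with fields `R_A`, `R_B`,
#'   `delta2` and the derived overall dynamic range `DR = max(R_A,R_B)/min(R_A,R_B)`.
#' @examples
#' conversion_factors(R_A = 1, R_B = 5, delta2 = 0.2)
#' @export
conversion_factors <- function(R_A, R_B, delta2) {
  stopifnot(is.numeric(R_A), is.numeric(R_B), is.numeric(delta2),
            length(R_A) == 1, length(R_B) == 1, length(delta2) == 1)
  if (!is.finite(R_A) || R_A <= 0) stop("R_A must be a positive finite number", call. = FALSE)
  if (!is.finite(R_B) || R_B <= 0) stop("R_B must be a positive finite number", call. = FALSE)
  if (!is.finite(delta2) || delta2 <= 0) stop("delta2 must be a positive finite number", call. = FALSE)
  if (R_A == R_B) stop("degenerate sensor: R_A equals R_B (ratio does not respond to state)", call. = FALSE)
  structure(list(R_A = R_A, R_B = R_B, delta2 = delta2,
                 DR = max(R_A, R_B) / min(R_A, R_B)),
            class = "conversion_factors")
}

#' @export
print.conversion_factors <- function(x, ...) {
  cat(sprintf("Conversion factors: R_A = %g, R_B = %g, delta2 = %g (overall DR = %g)\n",
              x$R_A, x$R_B, x$delta2, x$DR))
  invisible(x)
}

.as_factors <- function(f) {
  if (inherits(f, "biosensor")) return(f$factors)
  if (inherits(f, "conversion_factors")) return(f)
  stop("expected a 'conversion_factors' or 'biosensor' object", call. = FALSE)
}

#' Construct a two-state ratiometric biosensor
#'
#' Couples conversion factors with the sensor's chemistry: a midpoint
#' potential for redox sensors (Nernst map), a pKa for pH sensors
#' (Henderson--Hasselbalch map), or a pKd for ligand sensors.
#'
#' @param name Sensor label.
#' @param kind One of `"redox"`, `"pH"`, `"ligand"`.
#' @param factors A [conversion_factors()] object (alternatively pass `R_A`,
#'   `R_B`, `delta2`).
#' @param R_A,R_B,delta2 Used when `factors` is not given.
#' @param e0 Midpoint potential in mV (redox only): the potential at which
#'   the sensor is 50% oxidized.
#' @param pKa Acid dissociation constant (pH only).
#' @param pKd Negative log10 of the dissociation constant in Molar (ligand only).
#' @param z Number of electrons transferred (redox only), default 2.
#' @param temperature Temperature in Kelvin (redox only), default 298.15.
#' @return An object of class `"biosensor"`.
#' @examples
#' biosensor("example-roGFP", "redox", R_A = 1, R_B = 5, delta2 = 0.2, e0 = -265)
#' biosensor("example-pH", "pH", R_A = 2, R_B = 0.5, delta2 = 1.5, pKa = 7)
#' @export
biosensor <- function(name, kind = c("redox", "pH", "ligand"), factors = NULL,
                      R_A = NULL, R_B = NULL, delta2 = NULL,
                      e0 = NULL, pKa = NULL, pKd = NULL,
                      z = 2L, temperature = 298.15) {
  kind <- match.arg(kind)
  if (is.null(factors)) {
    if (is.null(R_A) || is.null(R_B) || is.null(delta2))
      stop("provide either 'factors' or all of R_A, R_B, delta2", call. = FALSE)
    factors <- conversion_factors(R_A, R_B, delta2)
  } else {
    factors <- .as_factors(factors)
  }
  given <- c(e0 = !is.null(e0), pKa = !is.null(pKa), pKd = !is.null(pKd))
  needed <- switch(kind, redox = "e0", pH = "pKa", ligand = "pKd")
  if (sum(given) != 1L || !given[[needed]])
    stop(sprintf("a '%s' sensor requires exactly the chemistry constant '%s'", kind, needed),
         call. = FALSE)
  chem <- switch(kind,
    redox = {
      stopifnot(is.numeric(e0), length(e0) == 1, is.finite(e0))
      if (!is.numeric(temperature) || temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
      z <- as.integer(z)
      if (is.na(z) || z < 1L) stop("z must be an integer >= 1", call. = FALSE)
      list(e0 = e0, z = z, temperature = temperature)
    },
    pH = {
      stopifnot(is.numeric(pKa), length(pKa) == 1, is.finite(pKa))
      list(pKa = pKa)
    },
    ligand = {
      stopifnot(is.numeric(pKd), length(pKd) == 1, is.finite(pKd))
      list(pKd = pKd)
    })
  structure(list(name = as.character(name), kind = kind, factors = factors,
                 chemistry = chem),
            class = "biosensor")
}

# the midpoint constant (e0 / pKa / pKd) in value units
.midpoint <- function(sensor) {
  switch(sensor$kind,
         redox = sensor$chemistry$e0,
         pH = sensor$chemistry$pKa,
         ligand = sensor$chemistry$pKd)
}

# units of the biochemical value
.value_unit <- function(kind) switch(kind, redox = "mV", pH = "pH units", ligand = "p[Ligand] units")

# +1 if value increases with state-B fraction, -1 otherwise
.value_direction <- function(kind) if (identical(kind, "ligand")) -1 else 1

#' @export
print.biosensor <- function(x, ...) {
  const <- switch(x$kind,
    redox = sprintf("E0' = %g mV (z = %d, T = %g K)",
                    x$chemistry$e0, x$chemistry$z, x$chemistry$temperature),
    pH = sprintf("pKa = %g", x$chemistry$pKa),
    ligand = sprintf("pKd = %g", x$chemistry$pKd))
  cat(sprintf("<biosensor> %s [%s]\n  %s\n  R_A = %g, R_B = %g, delta2 = %g (DR = %g)\n",
              x$name, x$kind, const,
              x$factors$R_A, x$factors$R_B, x$factors$delta2, x$factors$DR))
  invisible(x)
}

#' State-B fraction from a fluorescence ratio
#'
#' Inverts the ensemble mixing relation: the observed ratio of a mixed
#' ensemble is an intensity-weighted combination of the pure-state ratios, so
#' `fraction = (R - R_A) / ((R - R_A) + delta2 * (R_B - R))`.
#'
#' @param R Fluorescence ratio(s); must lie in the closed interval between
#'   `R_A` and `R_B` (the sensor's gamut).
#' @param factors A [conversion_factors()] or [biosensor()] object.
#' @return Fraction(s) in \[0, 1\] of molecules in state B; strictly monotone
#'   in `R`, with `fraction(R_A) = 0` and `fraction(R_B) = 1`.
#' @examples
#' f <- conversion_factors(1, 5, 0.2)
#' fraction_from_ratio(2, f)   # 0.625
#' @export
fraction_from_ratio <- function(R, factors) {
  f <- .as_factors(factors)
  lo <- min(f$R_A, f$R_B); hi <- max(f$R_A, f$R_B)
  if (any(!is.finite(R)) || any(R < lo) || any(R > hi))
    stop(sprintf("ratio out of gamut: R must lie within [%g, %g]", lo, hi), call. = FALSE)
  (R - f$R_A) / ((R - f$R_A) + f$delta2 * (f$R_B - R))
}

#' Fluorescence ratio from a state-B fraction
#'
#' Algebraic inverse of [fraction_from_ratio()].
#'
#' @param fraction State-B fraction(s) in \[0, 1\].
#' @inheritParams fraction_from_ratio
#' @return Ratio(s) in the sensor's gamut.
#' @export
ratio_from_fraction <- function(fraction, factors) {
  f <- .as_factors(factors)
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("fraction must lie within [0, 1]", call. = FALSE)
  (f$R_A * (1 - fraction) + f$delta2 * fraction * f$R_B) /
    ((1 - fraction) + f$delta2 * fraction)
}

#' Biochemical value from a state-B fraction
#'
#' Redox sensors use the Nernst equation,
#' `E = E0' - (RT/zF) * ln((1 - fraction)/fraction)` (reported in mV); pH
#' sensors use Henderson--Hasselbalch, `pH = pKa + log10(fraction/(1-fraction))`
#' with `fraction` the deprotonated fraction; ligand sensors use
#' `p[L] = pKd - log10(fraction/(1-fraction))` with `fraction` the bound
#' fraction, so that half occupancy occurs at `[L] = Kd`.
#'
#' @param fraction State-B fraction(s), strictly inside (0, 1).
#' @param sensor A [biosensor()].
#' @return Value(s) in mV (redox), pH units, or p\[Ligand\] units.
#' @export
value_from_fraction <- function(fraction, sensor) {
  stopifnot(inherits(sensor, "biosensor"))
  if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction >= 1))
    stop("saturated state: fraction must lie strictly inside (0, 1); the value is unbounded at 0 or 1",
         call. = FALSE)
  .value_from_fraction_raw(fraction, sensor)
}

# no saturation checks; fraction clipped inside the logs only
.value_from_fraction_raw <- function(fraction, sensor) {
  fc <- pmin(pmax(fraction, .FRACTION_CLIP), 1 - .FRACTION_CLIP)
  switch(sensor$kind,
    redox = sensor$chemistry$e0 -
      .nernst_mV(sensor$chemistry$temperature, sensor$chemistry$z) * log((1 - fc) / fc),
    pH = sensor$chemistry$pKa + log10(fc / (1 - fc)),
    ligand = sensor$chemistry$pKd - log10(fc / (1 - fc)))
}

#' State-B fraction from a biochemical value
#'
#' Inverse of [value_from_fraction()]; defined for every finite value.
#'
#' @param value Biochemical value(s) in sensor units.
#' @inheritParams value_from_fraction
#' @return Fraction(s) strictly inside (0, 1).
#' @export
fraction_from_value <- function(value, sensor) {
  stopifnot(inherits(sensor, "biosensor"))
  if (any(!is.finite(value))) stop("value must be finite", call. = FALSE)
  switch(sensor$kind,
    redox = {
      k <- .nernst_mV(sensor$chemistry$temperature, sensor$chemistry$z)
      1 / (1 + exp((sensor$chemistry$e0 - value) / k))
    },
    pH = 1 / (1 + 10^(sensor$chemistry$pKa - value)),
    ligand = 1 / (1 + 10^(value - sensor$chemistry$pKd)))
}

#' Biochemical value from a fluorescence ratio, and back
#'
#' Compositions of the fraction maps. `value_from_ratio()` raises the
#' saturation error at the gamut endpoints (where the value is unbounded);
#' `ratio_from_value()` is defined for every finite value.
#'
#' @inheritParams fraction_from_ratio
#' @inheritParams value_from_fraction
#' @param value Biochemical value(s).
#' @return Value(s) or ratio(s).
#' @examples
#' s <- biosensor("demo", "redox", R_A = 1, R_B = 5, delta2 = 0.2, e0 = -265)
#' value_from_ratio(2, s)           # about -258.4 mV
#' ratio_from_value(-265, s)        # midpoint ratio (R_A + delta2*R_B)/(1 + delta2)
#' @export
value_from_ratio <- function(R, sensor) {
  stopifnot(inherits(sensor, "biosensor"))
  value_from_fraction(fraction_from_ratio(R, sensor$factors), sensor)
}

#' @rdname value_from_ratio
#' @export
ratio_from_value <- function(value, sensor) {
  stopifnot(inherits(sensor, "biosensor"))
  ratio_from_fraction(fraction_from_value(value, sensor), sensor)
}

# Extended value-from-ratio used by error propagation: a ratio outside the
# gamut maps to the signed infinite value limit instead of an error, and the
# gamut endpoints map to the same limits (saturation).
.value_from_ratio_ext <- function(R, sensor) {
  f <- sensor$factors
  lo <- min(f$R_A, f$R_B); hi <- max(f$R_A, f$R_B)
  dirR <- sign(f$R_B - f$R_A)              # does R grow with fraction?
  dirV <- .value_direction(sensor$kind)    # does value grow with fraction?
  out <- numeric(length(R))
  below <- R <= lo; above <- R >= hi
  interior <- !below & !above
  # beyond the state-A end the fraction limit is 0; beyond state B it is 1
  at_B <- (above & dirR > 0) | (below & dirR < 0)
  out[at_B]  <- dirV * Inf
  out[(below | above) & !at_B] <- -dirV * Inf
  if (any(interior)) {
    frac <- (R[interior] - f$R_A) / ((R[interior] - f$R_A) + f$delta2 * (f$R_B - R[interior]))
    out[interior] <- .value_from_fraction_raw(frac, sensor)
  }
  out
}

#' Default grid of biochemical values for a sensor kind
#'
#' Redox: -450 to 0 mV in 0.1 mV steps; pH: 0 to 14 in 0.005 steps;
#' ligand: p\[Ligand\] 0 to 12 in 0.005 steps.
#'
#' @param kind Sensor kind or a [biosensor()].
#' @param lower,upper,step Optional overrides.
#' @return Numeric vector of values.
#' @export
value_grid <- function(kind, lower = NULL, upper = NULL, step = NULL) {
  if (inherits(kind, "biosensor")) kind <- kind$kind
  kind <- match.arg(kind, c("redox", "pH", "ligand"))
  d <- switch(kind,
              redox = c(-450, 0, 0.1),
              pH = c(0, 14, 0.005),
              ligand = c(0, 12, 0.005))
  lower <- if (is.null(lower)) d[1] else lower
  upper <- if (is.null(upper)) d[2] else upper
  step  <- if (is.null(step))  d[3] else step
  if (!(lower < upper) || !(step > 0)) stop("grid requires lower < upper and step > 0", call. = FALSE)
  seq(lower, upper, by = step)
}

# round half away from zero; used only at the presentation layer
.round_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# presentation rounding convention: integers for mV, 2 decimals otherwise
.present_value <- function(x, kind) {
  if (identical(kind, "redox")) .round_away(x, 0) else .round_away(x, 2)
}
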