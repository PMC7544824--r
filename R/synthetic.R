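# Synthetic fixtures: Gaussian-peak two-state spectra, parametric sensors,
# zero-median multiplicative ratio errors, and simulated noisy measurements.
# Every module of the package is testable against these with no external data.

#' Gaussian spectral peak
#'
#' @param center Peak center in nm.
#' @param width Peak standard deviation in nm (> 0).
#' @param amplitude Peak amplitude in a.u. (>= 0).
#' @return A list of class `"gaussian_peak"`.
#' @export
gaussian_peak <- function(center, width, amplitude = 1) {
  stopifnot(is.numeric(center), is.numeric(width), is.numeric(amplitude))
  if (width <= 0) stop("peak width must be > 0", call. = FALSE)
  if (amplitude < 0) stop("peak amplitude must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "gaussian_peak")
}

.eval_peaks <- function(peaks, wavelengths) {
  if (inherits(peaks, "gaussian_peak")) peaks <- list(peaks)
  y <- numeric(length(wavelengths))
  for (p in peaks) {
    stopifnot(inherits(p, "gaussian_peak"))
    y <- y + p$amplitude * exp(-0.5 * ((wavelengths - p$center) / p$width)^2)
  }
  y
}

#' Synthetic two-state spectrum from Gaussian peaks
#'
#' Each state's intensity is a sum of Gaussian peaks sampled on a wavelength
#' grid; deterministic given its inputs. The exact band integral of a single
#' peak has the closed form `amplitude * width * sqrt(2*pi) * (Phi(hi) - Phi(lo))`
#' (standardized band edges), which serves as an independent oracle for the
#' trapezoidal band integration.
#'
#' @param peaks_A,peaks_B Lists of [gaussian_peak()]s (or a single peak).
#' @param wavelengths Sampling grid in nm, strictly increasing.
#' @param axis `"excitation"` or `"emission"`.
#' @return A [two_state_spectrum()].
#' @export
make_spectrum <- function(peaks_A, peaks_B, wavelengths = seq(350, 550, by = 1),
                          axis = c("excitation", "emission")) {
  two_state_spectrum(wavelengths,
                     .eval_peaks(peaks_A, wavelengths),
                     .eval_peaks(peaks_B, wavelengths),
                     axis = match.arg(axis))
}

#' Closed-form band integral of Gaussian peaks
#'
#' Independent analytic oracle for [band_intensity()] on [make_spectrum()]
#' fixtures.
#'
#' @param peaks List of [gaussian_peak()]s (or one peak).
#' @param band A [wavelength_band()] or `(low, high)` pair.
#' @return Exact integral of the peak sum over the band.
#' @export
gaussian_band_integral <- function(peaks, band) {
  band <- .as_band(band)
  if (inherits(peaks, "gaussian_peak")) peaks <- list(peaks)
  total <- 0
  for (p in peaks) {
    total <- total + p$amplitude * p$width * sqrt(2 * pi) *
      (stats::pnorm((band$high - p$center) / p$width) -
       stats::pnorm((band$low - p$center) / p$width))
  }
  total
}

#' Synthetic parametric biosensor
#'
#' Convenience constructor for randomized and fixture sensors. Defaults echo
#' a high-performing in vivo glutathione redox sensor: ratio endpoints 1 and
#' 7.8 (overall dynamic range 7.8) and midpoint potential -265 mV.
#'
#' @param kind `"redox"`, `"pH"`, or `"ligand"`.
#' @param constant Chemistry constant (e0 in mV / pKa / pKd); defaults:
#'   -265 mV, 7, 6.
#' @param R_A,R_B,delta2 Conversion factors.
#' @param mirror If `TRUE`, swap `R_A` and `R_B` (a sensor whose ratio
#'   decreases upon activation), for symmetry tests.
#' @param name Sensor label.
#' @param ... Passed to [biosensor()] (e.g. `z`, `temperature`).
#' @return A [biosensor()].
#' @export
make_sensor <- function(kind = c("redox", "pH", "ligand"), constant = NULL,
                        R_A = 1, R_B = 7.8, delta2 = 0.2, mirror = FALSE,
                        name = "synthetic", ...) {
  kind <- match.arg(kind)
  if (is.null(constant)) constant <- switch(kind, redox = -265, pH = 7, ligand = 6)
  if (mirror) { tmp <- R_A; R_A <- R_B; R_B <- tmp }
  switch(kind,
         redox = biosensor(name, "redox", R_A = R_A, R_B = R_B, delta2 = delta2,
                           e0 = constant, ...),
         pH = biosensor(name, "pH", R_A = R_A, R_B = R_B, delta2 = delta2,
                        pKa = constant, ...),
         ligand = biosensor(name, "ligand", R_A = R_A, R_B = R_B, delta2 = delta2,
                            pKd = constant, ...))
}

#' Random valid sensors for property tests
#'
#' Draws conversion factors log-uniformly (R endpoints spanning up to a
#' 10-fold dynamic range, delta2 in 0.05--5) and a midpoint constant in a
#' kind-appropriate range; orientation (R increasing or decreasing with the
#' state fraction) is random.
#'
#' @param n Number of sensors.
#' @param kind Sensor kind.
#' @return List of [biosensor()]s.
#' @export
random_sensors <- function(n, kind = c("redox", "pH", "ligand")) {
  kind <- match.arg(kind)
  lapply(seq_len(n), function(i) {
    R_A <- exp(stats::runif(1, log(0.2), log(5)))
    DR <- exp(stats::runif(1, log(1.5), log(10)))
    R_B <- if (stats::runif(1) < 0.5) R_A * DR else R_A / DR
    delta2 <- exp(stats::runif(1, log(0.05), log(5)))
    constant <- switch(kind,
                       redox = stats::runif(1, -320, -220),
                       pH = stats::runif(1, 5, 9),
                       ligand = stats::runif(1, 3, 9))
    make_sensor(kind, constant, R_A = R_A, R_B = R_B, delta2 = delta2,
                name = sprintf("rand-%s-%03d", kind, i))
  })
}

#' Sample centered multiplicative fold errors
#'
#' Draws `eps` values (as in `R_Obs = R_True * (1 + eps)`) from a distribution
#' symmetric about zero whose central 95% interval is `(-spread, +spread)`.
#'
#' @param n Number of draws (>= 1).
#' @param spread Target central-95% half-width, default 0.028.
#' @param distribution `"normal"`, `"t"` (scaled Student t), or `"two_point"`
#'   (+/- spread with equal probability).
#' @param df Degrees of freedom for the t distribution.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of fold errors.
#' @export
sample_fold_errors <- function(n, spread = 0.028,
                               distribution = c("normal", "t", "two_point"),
                               df = 5, seed = NULL) {
  distribution <- match.arg(distribution)
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1", call. = FALSE)
  if (spread < 0) stop("spread must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  switch(distribution,
         normal = stats::rnorm(n, 0, spread / stats::qnorm(0.975)),
         t = stats::rt(n, df) * spread / stats::qt(0.975, df),
         two_point = sample(c(-spread, spread), n, replace = TRUE))
}

#' Simulate noisy ratiometric measurements
#'
#' Maps each true value forward to its true ratio, multiplies by `(1 + eps)`
#' with `eps` drawn by [sample_fold_errors()], and inverts back to a value.
#' Draws whose perturbed ratio exits the sensor gamut are flagged as
#' saturated (observed value `+/-Inf`), never silently dropped.
#'
#' @param sensor A [biosensor()].
#' @param true_values Vector of true biochemical values.
#' @param n_per_value Number of simulated observations per true value.
#' @param spread,distribution,df Passed to [sample_fold_errors()].
#' @param seed Optional integer seed.
#' @return Data frame with columns `true`, `observed`, `saturated`.
#' @export
simulate_measurements <- function(sensor, true_values, n_per_value = 1000,
                                  spread = 0.028, distribution = "normal",
                                  df = 5, seed = NULL) {
  stopifnot(inherits(sensor, "biosensor"))
  if (!is.null(seed)) set.seed(seed)
  n_tot <- length(true_values) * n_per_value
  eps <- sample_fold_errors(n_tot, spread = spread, distribution = distribution, df = df)
  true <- rep(true_values, each = n_per_value)
  R_obs <- ratio_from_value(true, sensor) * (1 + eps)
  obs <- .value_from_ratio_ext(R_obs, sensor)
  data.frame(true = true, observed = obs, saturated = !is.finite(obs))
}
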