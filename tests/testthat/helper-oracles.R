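# Independent oracles used across test files. These deliberately avoid the
# closed-form inverse paths they are used to check.

# invert ratio_from_value by bisection on the value axis (no closed form)
bisect_value_from_ratio <- function(R, sensor, tol = 1e-9) {
  span <- switch(sensor$kind, redox = 600, pH = 20, ligand = 20)
  lo <- .midpoint_of(sensor) - span
  hi <- .midpoint_of(sensor) + span
  increasing <- ratio_from_value(hi, sensor) > ratio_from_value(lo, sensor)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    too_low <- if (increasing) ratio_from_value(mid, sensor) < R else ratio_from_value(mid, sensor) > R
    lo <- ifelse(too_low, mid, lo)
    hi <- ifelse(too_low, hi, mid)
  }
  (lo + hi) / 2
}

.midpoint_of <- function(sensor) {
  switch(sensor$kind,
         redox = sensor$chemistry$e0,
         pH = sensor$chemistry$pKa,
         ligand = sensor$chemistry$pKd)
}

# distribution-free Monte-Carlo band for a true quantile: the order
# statistics k +/- 3*sqrt(n p (1-p)) of the sample bracket it
mc_quantile_band <- function(x, p, nse = 3) {
  n <- length(x)
  xs <- sort(x)
  k <- n * p
  half <- nse * sqrt(n * p * (1 - p))
  lo <- max(1L, floor(k - half))
  hi <- min(n, ceiling(k + half))
  c(xs[lo], xs[hi])
}

# equal-weight mixture quantile by brute-force resampling of experiments
resample_mixture_quantile <- function(experiments, probs, n_draws = 2e5) {
  k <- length(experiments)
  picks <- sample.int(k, n_draws, replace = TRUE)
  draws <- vapply(picks, function(i) sample(experiments[[i]], 1L), numeric(1))
  stats::quantile(draws, probs, names = FALSE)
}

# a small well-behaved redox sensor reused in many tests
demo_sensor <- function() {
  biosensor("demo", "redox", R_A = 1, R_B = 5, delta2 = 0.2, e0 = -265)
}

# sum-of-Gaussians two-state fixture with well-separated peaks
demo_gaussian_fixture <- function(step = 1) {
  peaks_A <- list(gaussian_peak(400, 12, 5), gaussian_peak(470, 18, 1.2))
  peaks_B <- list(gaussian_peak(400, 12, 1.5), gaussian_peak(480, 15, 4))
  make_spectrum(peaks_A, peaks_B, wavelengths = seq(340, 560, by = step))
}

# presentation rounding: half away from zero (re-stated here so tests do not
# reach into package internals)
round_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# empty ranges nest inside everything
interval_nested <- function(inner, outer) {
  is.null(inner) || (!is.null(outer) && inner[1] >= outer[1] && inner[2] <= outer[2])
}
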