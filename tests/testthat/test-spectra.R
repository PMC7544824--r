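# Band integration, spectra-derived conversion factors, optimal band search.

test_that("band integration: flat region, partition additivity, edge interpolation", {
  wl <- seq(300, 400, by = 1)
  sp <- two_state_spectrum(wl, rep(1, length(wl)), rep(2, length(wl)))
  expect_equal(band_intensity(sp, "A", c(350, 360)), 10)
  expect_equal(band_intensity(sp, "B", c(350, 360)), 20)
  # edges between tabulated points
  expect_equal(band_intensity(sp, "A", c(350.3, 360.7)), 10.4)
  # splitting a band sums to the whole
  whole <- band_intensity(sp, "A", c(310, 390))
  expect_equal(band_intensity(sp, "A", c(310, 347.2)) + band_intensity(sp, "A", c(347.2, 390)),
               whole)
  expect_error(band_intensity(sp, "A", c(500, 520)), "does not overlap")
})

test_that("trapezoidal integrals match the closed-form Gaussian oracle", {
  peaks_A <- list(gaussian_peak(400, 12, 5), gaussian_peak(470, 18, 1.2))
  sp <- demo_gaussian_fixture(step = 1)
  for (band in list(c(390, 410), c(470, 490), c(360, 520))) {
    got <- band_intensity(sp, "A", band)
    want <- gaussian_band_integral(peaks_A, band)
    expect_equal(got, want, tolerance = 1e-3)  # 0.1%
  }
  # and against a fine-grid numeric quadrature oracle
  fine <- demo_gaussian_fixture(step = 0.01)
  expect_equal(band_intensity(sp, "B", c(430, 500)),
               band_intensity(fine, "B", c(430, 500)), tolerance = 1e-3)
})

test_that("factors_from_spectra matches hand-computed Gaussian integrals", {
  peaks_A <- list(gaussian_peak(400, 12, 5), gaussian_peak(470, 18, 1.2))
  peaks_B <- list(gaussian_peak(400, 12, 1.5), gaussian_peak(480, 15, 4))
  sp <- demo_gaussian_fixture()
  b1 <- c(390, 410); b2 <- c(470, 490)
  fac <- factors_from_spectra(sp, b1, b2)
  iA1 <- gaussian_band_integral(peaks_A, b1); iA2 <- gaussian_band_integral(peaks_A, b2)
  iB1 <- gaussian_band_integral(peaks_B, b1); iB2 <- gaussian_band_integral(peaks_B, b2)
  expect_equal(fac$R_A, iA1 / iA2, tolerance = 5e-3)   # 0.5%
  expect_equal(fac$R_B, iB1 / iB2, tolerance = 5e-3)
  expect_equal(fac$delta2, iB2 / iA2, tolerance = 5e-3)
})

test_that("degenerate and scaled spectra behave as required", {
  wl <- seq(350, 550, by = 1)
  yA <- exp(-0.5 * ((wl - 420) / 20)^2)
  # state B globally proportional to state A: nonresponsive sensor
  sp_deg <- two_state_spectrum(wl, yA, 3 * yA)
  expect_error(factors_from_spectra(sp_deg, c(390, 410), c(470, 490)), "degenerate")
  # rescaling both states leaves all three factors unchanged
  sp <- demo_gaussian_fixture()
  sp_scaled <- two_state_spectrum(sp$wavelengths, 7.3 * sp$intensity_A, 7.3 * sp$intensity_B)
  f1 <- factors_from_spectra(sp, c(390, 410), c(470, 490))
  f2 <- factors_from_spectra(sp_scaled, c(390, 410), c(470, 490))
  expect_equal(f1$R_A, f2$R_A); expect_equal(f1$R_B, f2$R_B); expect_equal(f1$delta2, f2$delta2)
  # an all-zero state yields the zero-intensity error
  sp0 <- two_state_spectrum(wl, yA, rep(0, length(wl)))
  expect_error(factors_from_spectra(sp0, c(390, 410), c(470, 490)), "positive")
})

test_that("factors are robust to 2x downsampling of a smooth spectrum", {
  f1 <- factors_from_spectra(demo_gaussian_fixture(1), c(390, 410), c(470, 490))
  f2 <- factors_from_spectra(demo_gaussian_fixture(2), c(390, 410), c(470, 490))
  expect_equal(f1$R_A, f2$R_A, tolerance = 0.01)
  expect_equal(f1$R_B, f2$R_B, tolerance = 0.01)
  expect_equal(f1$delta2, f2$delta2, tolerance = 0.01)
})

test_that("swapping the bands inverts the factors and preserves inaccuracy", {
  sp <- demo_gaussian_fixture()
  b1 <- c(390, 410); b2 <- c(470, 490)
  f12 <- factors_from_spectra(sp, b1, b2)
  f21 <- factors_from_spectra(sp, b2, b1)
  expect_equal(f21$R_A, 1 / f12$R_A)
  expect_equal(f21$R_B, 1 / f12$R_B)
  iA1 <- band_intensity(sp, "A", b1); iB1 <- band_intensity(sp, "B", b1)
  expect_equal(f21$delta2, iB1 / iA1)
  s12 <- biosensor("fwd", "redox", factors = f12, e0 = -265)
  s21 <- biosensor("swp", "redox", factors = f21, e0 = -265)
  g <- seq(-310, -220, by = 0.5)
  # swapping the bands maps the ratio R to 1/R, so a fold error eps on the
  # swapped ratio corresponds to 1/(1 + eps) - 1 on the original; with the
  # transformed interval the inaccuracy curves coincide exactly
  l <- 0.028; u <- 0.028
  swapped_err <- error_interval(-u / (1 + u), l / (1 - l))
  expect_equal(inaccuracy(g, s12, error_interval(-l, u)),
               inaccuracy(g, s21, swapped_err), tolerance = 1e-9)
  # with the same untransformed interval they agree only to first order
  expect_equal(inaccuracy(g, s12, 0.028), inaccuracy(g, s21, 0.028),
               tolerance = 0.05)
})

test_that("band-pair optimization equals independent brute-force enumeration", {
  sp <- demo_gaussian_fixture(2)
  grid <- value_grid("redox", -400, -150, 0.5)
  res <- optimize_bands(sp, "redox", -265, 0.028, threshold = 3,
                        min_width = 20, step = 15, grid = grid)
  expect_gt(res$n_pairs, 50)  # a non-trivial search space
  # brute force: enumerate the same lattice directly
  lows <- seq(340, 560 - 20, by = 15)
  best_w <- -1; best <- NULL
  for (i in seq_along(lows)) for (j in seq_along(lows)) {
    if (j <= i) next
    fac <- tryCatch(factors_from_spectra(sp, c(lows[i], lows[i] + 20), c(lows[j], lows[j] + 20)),
                    error = function(e) NULL)
    if (is.null(fac)) next
    s <- biosensor("bf", "redox", factors = fac, e0 = -265)
    sr <- suppressWarnings(suitable_range(s, 0.028, 3, grid = grid))
    w <- if (is.null(sr$interval)) 0 else diff(sr$interval)
    if (w > best_w + 1e-9) { best_w <- w; best <- c(lows[i], lows[j]) }
  }
  expect_equal(res$objective, best_w, tolerance = 1e-6)
  expect_equal(c(res$band1$low, res$band2$low), best)
  # a search space with a single valid pair returns that pair
  res1 <- optimize_bands(sp, "redox", -265, 0.028, threshold = 3,
                         min_width = 105, step = 110, grid = grid)
  expect_equal(res1$n_pairs, 1)
})

test_that("the same sensor in two modalities yields different predicted accuracy", {
  # dual-modality fixture: an excitation-ratio and an emission-ratio readout
  # of one pH sensor with a shared pKa but different spectral contrast
  exc <- make_spectrum(list(gaussian_peak(400, 15, 4), gaussian_peak(480, 15, 1)),
                       list(gaussian_peak(400, 15, 1), gaussian_peak(480, 15, 4)),
                       axis = "excitation")
  emi <- make_spectrum(list(gaussian_peak(510, 12, 3), gaussian_peak(560, 20, 1)),
                       list(gaussian_peak(510, 12, 2), gaussian_peak(560, 20, 1.6)),
                       wavelengths = seq(480, 650, by = 1), axis = "emission")
  f_exc <- factors_from_spectra(exc, c(390, 410), c(470, 490))
  f_emi <- factors_from_spectra(emi, c(500, 520), c(550, 570))
  s_exc <- biosensor("dual-ex", "pH", factors = f_exc, pKa = 6.9)
  s_emi <- biosensor("dual-em", "pH", factors = f_emi, pKa = 6.9)
  g <- value_grid("pH")
  expect_false(isTRUE(all.equal(min(inaccuracy(g, s_exc, 0.028)),
                                min(inaccuracy(g, s_emi, 0.028)))))
})

test_that("spectra CSV round-trips through the documented format", {
  sp <- demo_gaussian_fixture(5)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  # prepend a comment line, which readers must skip
  txt <- readLines(path)
  writeLines(c("# synthetic fixture", txt), path)
  back <- read_spectrum_csv(path, axis = "excitation")
  expect_equal(back$wavelengths, sp$wavelengths)
  expect_equal(back$intensity_A, sp$intensity_A)
  expect_equal(back$intensity_B, sp$intensity_B)
})
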