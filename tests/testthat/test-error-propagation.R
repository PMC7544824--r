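# Propagation of multiplicative R errors into bounds, inaccuracy curves and
# suitable ranges.

test_that("observed_bounds: identity at zero error, hand value, gamut exit", {
  s <- demo_sensor()
  v <- value_from_ratio(2, s)
  expect_equal(observed_bounds(v, s, error_interval(0, 0)), c(v, v))
  # hand propagation of R = 2 * (1 -/+ 0.028) through the closed form
  b <- observed_bounds(v, s, 0.028)
  expect_equal(b[1], value_from_ratio(2 * 0.972, s))
  expect_equal(b[2], value_from_ratio(2 * 1.028, s))
  expect_equal(b, c(-259.4157, -257.4958), tolerance = 1e-4)
  expect_true(b[1] <= v && v <= b[2])
  # deep saturation: upper perturbed ratio exits the gamut
  v_sat <- value_from_ratio(4.95, s)
  expect_equal(observed_bounds(v_sat, s, 0.028)[2], Inf)
  # for a ligand sensor the bound that saturates is the LOWER p[L] bound
  sl <- make_sensor("ligand", 6, R_A = 1, R_B = 5, delta2 = 0.2)
  vl <- value_from_ratio(4.95, sl)
  expect_equal(observed_bounds(vl, sl, 0.028)[1], -Inf)
})

test_that("inaccuracy is the worst-case bound deviation and is monotone in error width", {
  s <- demo_sensor()
  grid <- seq(-300, -230, by = 0.5)
  expect_equal(inaccuracy(grid, s, error_interval(0, 0)), rep(0, length(grid)))
  v <- value_from_ratio(2, s)
  ia <- inaccuracy(v, s, 0.028)
  b <- observed_bounds(v, s, 0.028)
  expect_equal(ia, max(abs(v - b)))
  expect_equal(ia, 0.9779, tolerance = 1e-3)
  expect_true(all(inaccuracy(grid, s, 0.5) > inaccuracy(grid, s, 0.028)))
  # halving the interval never increases any point
  expect_true(all(inaccuracy(grid, s, 0.014) <= inaccuracy(grid, s, 0.028)))
})

test_that("inaccuracy_curve is pointwise consistent and diverges at the extremes", {
  s <- demo_sensor()
  cur <- inaccuracy_curve(s, 0.028)
  expect_equal(cur$inaccuracy, inaccuracy(cur$values, s, 0.028))
  expect_equal(cur$inaccuracy[1], Inf)
  expect_equal(cur$inaccuracy[length(cur$inaccuracy)], Inf)
  # minimum is finite and interior (brute-force scan)
  i <- which.min(cur$inaccuracy)
  expect_true(is.finite(cur$inaccuracy[i]))
  expect_true(i > 1 && i < length(cur$values))
  df <- as.data.frame(cur)
  expect_named(df, c("value", "inaccuracy"))
})

test_that("asymmetric error intervals propagate without symmetrization", {
  s <- demo_sensor()
  v <- value_from_ratio(2, s)
  b <- observed_bounds(v, s, error_interval(-0.01, 0.05))
  expect_equal(b[1], value_from_ratio(2 * 0.99, s))
  expect_equal(b[2], value_from_ratio(2 * 1.05, s))
  expect_gt(abs(b[2] - v), abs(b[1] - v))
})

test_that("Monte-Carlo quantile propagation reproduces observed_bounds", {
  set.seed(21)
  combos <- expand.grid(i = 1:10, err = c(0.028, 0.1))
  kinds <- rep(c("redox", "pH"), each = 5)
  sensors <- lapply(seq_along(kinds), function(i)
    make_sensor(kinds[i],
                constant = if (kinds[i] == "redox") runif(1, -300, -230) else runif(1, 6, 8),
                R_A = exp(runif(1, log(0.5), log(2))),
                R_B = exp(runif(1, log(0.5), log(2))) * runif(1, 4, 9),
                delta2 = exp(runif(1, log(0.1), log(2))),
                name = sprintf("mc-%02d", i)))
  n <- 1e5
  for (r in seq_len(nrow(combos))) {
    s <- sensors[[combos$i[r]]]
    half <- combos$err[r]
    sd_eps <- half / qnorm(0.975)  # central 95% interval = (-half, +half)
    # pick a true value whose ratio stays inside the gamut out to 5 sd of eps
    f <- s$factors
    lo <- min(f$R_A, f$R_B); hi <- max(f$R_A, f$R_B)
    R_ok <- c(lo / (1 - 5 * sd_eps), hi / (1 + 5 * sd_eps))
    v_ok <- sort(value_from_ratio(R_ok, s))
    v <- runif(1, v_ok[1], v_ok[2])
    obs <- value_from_ratio(ratio_from_value(v, s) * (1 + pmax(pmin(rnorm(n, 0, sd_eps),
                                                                    5 * sd_eps), -5 * sd_eps)), s)
    b <- observed_bounds(v, s, half)
    band_lo <- mc_quantile_band(obs, 0.025, nse = 4)
    band_hi <- mc_quantile_band(obs, 0.975, nse = 4)
    expect_gte(b[1], band_lo[1]); expect_lte(b[1], band_lo[2])
    expect_gte(b[2], band_hi[1]); expect_lte(b[2], band_hi[2])
  }
})

test_that("suitable ranges nest in threshold and in error width, and can be empty", {
  set.seed(22)
  for (s in c(random_sensors(4, "redox"), random_sensors(3, "ligand"))) {
    step <- if (s$kind == "redox") c(1, 2, 5) else c(0.05, 0.1, 0.25)
    rs <- lapply(step, function(t) suitable_range(s, 0.028, t)$interval)
    expect_false(is.null(rs[[3]]))  # the loosest threshold is attainable
    expect_true(interval_nested(rs[[1]], rs[[2]]))
    expect_true(interval_nested(rs[[2]], rs[[3]]))
    # shrinking the error widens the range at fixed threshold
    wider <- suitable_range(s, 0.014, step[2])$interval
    expect_true(interval_nested(rs[[2]], wider))
  }
  expect_null(suitable_range(demo_sensor(), 0.5, 0.001)$interval)
  expect_error(suitable_range(demo_sensor(), 0.028, -1), "positive")
})

test_that("suitable-range endpoints sit on the threshold and interior satisfies it", {
  s <- demo_sensor()
  sr <- suitable_range(s, 0.028, 2)
  expect_equal(inaccuracy(sr$interval[1], s, 0.028), 2, tolerance = 1e-2)
  expect_equal(inaccuracy(sr$interval[2], s, 0.028), 2, tolerance = 1e-2)
  probes <- seq(sr$interval[1], sr$interval[2], length.out = 101)[2:100]
  expect_true(all(inaccuracy(probes, s, 0.028) <= 2 + 1e-6))
})

test_that("raising the overall dynamic range lowers the minimum inaccuracy", {
  base <- make_sensor("redox", -265, R_A = 1, R_B = 3, delta2 = 0.3)
  high <- make_sensor("redox", -265, R_A = 1, R_B = 9, delta2 = 0.3)
  g <- value_grid("redox")
  expect_lt(min(inaccuracy(g, high, 0.028)), min(inaccuracy(g, base, 0.028)))
})

test_that("empirical_error_interval: degenerate, normal, and mixture cases", {
  expect_equal(empirical_error_interval(list(rep(0, 10)))$lower, 0)
  expect_equal(empirical_error_interval(list(rep(0, 10)))$upper, 0)
  set.seed(23)
  ei <- empirical_error_interval(list(rnorm(1e5, 0, 0.01)))
  expect_equal(ei$lower, -0.0196, tolerance = 0.05)
  expect_equal(ei$upper, 0.0196, tolerance = 0.05)
  # two experiments of very different size get equal weight
  set.seed(24)
  e1 <- rnorm(10, 0, 0.01); e2 <- rnorm(1e4, 0, 0.05)
  ei2 <- empirical_error_interval(list(e1, e2))
  oracle <- resample_mixture_quantile(list(e1, e2), c(0.025, 0.975))
  expect_equal(ei2$lower, oracle[1], tolerance = 0.1)
  expect_equal(ei2$upper, oracle[2], tolerance = 0.1)
  # and is far from the pooled (size-weighted) quantiles, which e2 dominates
  pooled <- quantile(c(e1, e2), 0.975, names = FALSE)
  expect_lt(ei2$upper, pooled)
  expect_error(empirical_error_interval(list()), "non-empty")
  expect_error(empirical_error_interval(list(0.1)), "at least 2")
})

test_that("curves and ranges serialize to CSV and JSON losslessly", {
  s <- demo_sensor()
  cur <- inaccuracy_curve(s, 0.028, grid = seq(-280, -240, by = 1))
  csv <- tempfile(fileext = ".csv")
  export_table(cur, csv)
  back <- read.csv(csv)
  expect_equal(back$value, cur$values)
  expect_equal(back$inaccuracy, cur$inaccuracy)
  js <- tempfile(fileext = ".json")
  export_table(suitable_range(s, 0.028, 2), js, format = "json")
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$lower, suitable_range(s, 0.028, 2)$interval[1])
})
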