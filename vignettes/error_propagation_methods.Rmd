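---
title: "Methods: propagating ratio errors through two-state biosensor calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propagating ratio errors through two-state biosensor calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensorspan)
```

## The two-state model

A ratiometric biosensor interconverts between a low state A and a high
state B (reduced/oxidized, protonated/deprotonated, apo/bound). Its
readout is the ratio $R$ of fluorescence intensities integrated over two
wavelength bands. Three **conversion factors**, measurable from the
pure-state spectra, fully determine the calibration:

* $R_A$, $R_B$ — the ratio in the pure A and pure B states;
* $\delta_2$ — the B-to-A intensity ratio in the *second* band.

For a population with fraction $f$ of molecules in state B, band
intensities are linear mixtures of the pure-state intensities, which gives
the exact forward and inverse maps

$$
f \;=\; \frac{R - R_A}{(R - R_A) + \delta_2 (R_B - R)},
\qquad
R \;=\; \frac{R_A (1-f) + \delta_2 f R_B}{(1-f) + \delta_2 f}.
$$

$R$ is confined to the **gamut** $[\min(R_A,R_B), \max(R_A,R_B)]$ and the
map is strictly monotone on it. The fraction then maps to the biochemical
value by standard closed forms:

* redox: $E = E_0' - \dfrac{RT}{zF}\,1000 \ln\dfrac{1-f}{f}$ millivolts,
* pH: $\mathrm{pH} = \mathrm{p}K_a + \log_{10}\dfrac{f}{1-f}$,
* ligand: $\mathrm{p[L]} = \mathrm{p}K_d - \log_{10}\dfrac{f}{1-f}$
  (note this *decreases* as occupancy rises).

`biosensor()` bundles the factors with exactly one chemistry constant
(`e0`, `pKa`, or `pKd`); `value_from_ratio()` and `ratio_from_value()` are
the composed maps.

### Parameter defaults

* **Temperature** defaults to 298.15 K and **z** to 2 electrons (the
  glutathione couple sensed by roGFPs); both are per-sensor overridable.
  At these defaults the Nernst prefactor is 12.846 mV per natural log
  unit.
* $\delta_2$ is defined as state-B over state-A intensity in band 2. With
  $\delta_2 = 1$ the fraction–ratio map is linear; $\delta_2 \ne 1$ bends
  it and shifts where the sensor is most accurate.

## Error model and propagation

Measurement noise is a multiplicative **fold error**,
$R_\mathrm{obs} = R_\mathrm{true}(1+\varepsilon)$, summarised by the
central 95% interval $(\ell, u)$ of $\varepsilon$ (`error_interval()`;
a single number `e` is shorthand for the symmetric interval $(-e, +e)$).
The interval can be estimated from replicate measurements with
`empirical_error_interval()`, which gives every experiment equal total
weight in a weighted quantile (so one large experiment cannot swamp the
others) and widens the interval to include zero if the raw quantiles do
not bracket it.

Because the ratio-to-value map is strictly monotone, quantiles push
forward exactly: the central 95% interval of the *observed value* at true
value $v$ is obtained by mapping $R(v)(1+\ell)$ and $R(v)(1+u)$ through
the inverse calibration (`observed_bounds()`). The **inaccuracy** at $v$
is the larger absolute deviation of the two bounds from $v$. If a
perturbed ratio exits the gamut, the sensor saturates there and the
inaccuracy is reported as $+\infty$ — deliberately never clipped to a
large finite number, so saturation is unmistakable downstream.

No distributional assumption beyond the 95% interval is needed for the
bounds themselves; anything stronger (e.g. full coverage curves) would
require the full law of $\varepsilon$.

### Suitable range

`suitable_range()` returns the interval of true values where the
inaccuracy stays at or below a threshold. The implementation:

1. evaluates the inaccuracy on a coarse grid (defaults below);
2. collects maximal sub-threshold runs, merging runs separated by fewer
   than two grid steps (with a warning) — these are grid artefacts near
   tangency, not genuine holes;
3. if several islands remain, keeps the one containing the curve's
   minimum (the sensor's natural operating region) and warns;
4. refines each edge by bisection between the bracketing grid points to a
   tolerance of $10^{-3}$ value units.

Default grids are −450…0 mV in 0.1 mV steps (redox), 0…14 in 0.005 (pH),
and 0…12 in 0.005 (ligand) — wide enough to contain any physiological
operating range at a resolution far below reporting precision. Printed
results are rounded half-away-from-zero to integer mV / two decimals; all
stored values are full precision.

### A useful invariance

Jointly rescaling $(R_A, R_B)$ leaves every prediction unchanged — only
the dynamic range $DR = \max(R_A,R_B)/\min(R_A,R_B)$ and $\delta_2$
matter. Moreover the *width* of the suitable range depends only on $DR$
(and the threshold and error), while $\delta_2$ rigidly shifts the window
along the value axis. The test suite exploits this to generate random
sensors with $R_A = 1$ without loss of generality.

## Sensor comparison

For a panel of same-kind sensors, `best_sensor_curve()` takes the
pointwise minimum of the inaccuracy curves (ties within $10^{-9}$ value
units go to the earlier sensor in the list; points where every sensor is
saturated have no winner). `optimal_windows()` converts the winner
sequence into maximal runs, `coverage_gaps()` reports the runs where the
envelope exceeds a threshold, and `phase_diagram()` classifies each
(value, tolerated-inaccuracy) pair as feasible or not — the feasibility
boundary *is* the inaccuracy curve. Each sensor may carry its own error
interval (filter sets differ), passed as a named list.

## Spectra and band choice

`factors_from_spectra()` computes $R_A$, $R_B$, $\delta_2$ from a
two-state spectrum by trapezoidal integration over each band, with
linear interpolation at band edges that fall between samples. Factors are
rejected as degenerate when $|R_A - R_B| \le 10^{-9}\max(R_A,R_B)$, since
such a sensor carries no signal. `optimize_bands()` enumerates unordered
band pairs on a lattice of low edges (default step 5 nm) and widths
(default 10 nm), scoring each pair by the resulting suitable-range width
at the user's threshold; ties break to the smaller minimum inaccuracy,
then to enumeration order. The search is exhaustive rather than
heuristic: spectra are short vectors and the lattice keeps the pair count
in the hundreds.

## Synthetic fixtures

The `synthetic_fixtures` helpers exist to make honest tests and demos:

* `make_spectrum()` builds two-state spectra from sums of Gaussian peaks;
  `gaussian_band_integral()` is the matching closed-form oracle
  (`pnorm` differences), so trapezoidal integration is tested against an
  independent computation.
* `random_sensors()` draws log-uniform conversion factors with dynamic
  ranges between 1.5 and 10 and random orientation — wide enough to probe
  edge behaviour, narrow enough that every draw is a usable sensor.
* `sample_fold_errors()` draws fold errors from a normal, scaled Student
  t, or symmetric two-point law, scaled so the central 95% interval hits
  the requested spread; `simulate_measurements()` pushes them through a
  sensor and flags (never drops) saturated draws.

These generators are for validation and illustration. They make no claim
to model real instrument noise beyond its 95% fold-error interval, and
the two-point law in particular is a stress case, not a physical model.

## The bundled sensor database

`sensor_db()` loads `inst/extdata/sensor_db_synthetic.json`: redox, pH,
and ligand sensors whose midpoint constants come from the literature but
whose conversion factors are *reconstructed representative* values (each
record says so in its `note`). The database demonstrates the comparison
machinery on a realistic panel; it is not a calibration reference, and
analyses of a real instrument should use factors measured on that
instrument (`load_sensor_db()` reads the same JSON schema).

## Limitations

* Only two-state sensors are covered; probes with intermediate states or
  photoswitching violate the linear-mixture assumption.
* The error model is a single multiplicative fold error on $R$; additive
  background, bleaching drift, and band-correlated noise are out of
  scope.
* Propagation is of a 95% interval, not a full distribution; coverage at
  other levels requires re-estimating the interval at that level.
* Suitable-range islands other than the one containing the inaccuracy
  minimum are discarded (with a warning); multi-modal operating regions
  must be examined via `inaccuracy_curve()` directly.
* The band optimizer assumes the error interval is independent of the
  band choice, which holds only approximately when photon counts differ
  strongly between candidate bands.
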