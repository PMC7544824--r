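# sensorspan

Predict how measurement error limits the usable range of ratiometric,
two-state fluorescent biosensors.

Genetically encoded sensors such as the roGFP redox probes, ratiometric pH
indicators, and ligand sensors report a biochemical quantity through the
ratio `R` of fluorescence intensities in two wavelength bands. The sensor
itself is a two-state system: a calibration maps `R` to the fraction of
sensor molecules in the high state, and standard biochemistry
(the Nernst equation, Henderson–Hasselbalch, or a binding isotherm) maps
that fraction to a redox potential, pH, or ligand concentration.

Because those maps are steep near the sensor's saturation points, a small
relative error in `R` can translate into a large error in the inferred
biochemical value. `sensorspan` propagates an empirically determined
relative error in `R` through the exact calibration maps and answers, for
any sensor:

* How inaccurate is a measurement at each true value? (`inaccuracy_curve()`)
* Over which interval of values does the sensor stay within a chosen
  accuracy? (`suitable_range()`)
* Given a panel of sensors, which is the most accurate at each value, and
  where does *no* sensor suffice? (`optimal_windows()`, `coverage_gaps()`)
* How does the feasible region depend on the tolerated inaccuracy?
  (`phase_diagram()`)
* What do these quantities look like for a sensor characterised only by its
  two-state emission/excitation spectra, and which band pair is optimal?
  (`factors_from_spectra()`, `optimize_bands()`)

## The model

A sensor is summarised by three conversion factors measured from its
spectra: `R_A` and `R_B`, the ratios in the pure low and high states, and
`delta2`, the high-to-low intensity ratio in the second band. For an
observed ratio `R` in the gamut `[min(R_A,R_B), max(R_A,R_B)]`, the high-state
fraction is

```
f = (R - R_A) / ((R - R_A) + delta2 * (R_B - R))
```

and the biochemical value follows from `f` by the Nernst equation
(redox, `E = E0' - (RT/zF) ln((1-f)/f)` in mV), Henderson–Hasselbalch
(`pH = pKa + log10(f/(1-f))`), or the binding isotherm
(`p[L] = pKd - log10(f/(1-f))`).

Measurement noise is modelled as a multiplicative fold error,
`R_obs = R_true * (1 + eps)`, where the central 95% interval of `eps` —
for example (−2.8%, +2.8%) for a typical microscopy setup — is either
supplied directly or estimated from replicate measurements with
`empirical_error_interval()`. Because the ratio-to-value map is monotone,
the 95% interval of the observed value is obtained exactly by pushing the
two interval endpoints through the map; the **inaccuracy** at a true value
is the larger absolute deviation of those two bounds. Where a perturbed
ratio leaves the gamut the sensor is saturated and the inaccuracy is
reported as infinite, never clipped.

## Worked example

```r
library(sensorspan)

s <- biosensor("roGFP1-R12", "redox", R_A = 1, R_B = 7.8, delta2 = 0.171,
               e0 = -265)
s
#> <biosensor> roGFP1-R12 [redox]
#>   E0' = -265 mV (z = 2, T = 298.15 K)
#>   R_A = 1, R_B = 7.8, delta2 = 0.171 (DR = 7.8)

err <- error_interval(0.028)   # central 95% fold error of +/- 2.8%

# a ratio of 2 maps to about the sensor midpoint; +/-2.8% in R moves the
# inferred potential by under a millivolt there
value_from_ratio(2, s)
#> [1] -264.8942
observed_bounds(value_from_ratio(2, s), s, err)
#> [1] -265.7580 -264.0696

# the interval over which the sensor stays within 2 mV
suitable_range(s, err, 2)
#> Suitable range for roGFP1-R12 at <= 2 mV: [-284, -226]

# where the inaccuracy is lowest
summary(inaccuracy_curve(s, err))
#> Inaccuracy curve for roGFP1-R12 [redox]
#>   finite on 1143 of 4501 grid points
#>   minimum inaccuracy 0.7719 mV at value -255.1
```

Comparing the bundled panel of reconstructed redox sensors
(`sensor_db("redox")`) shows which probe to pick at each potential and
where the panel as a whole fails a 10 mV requirement:

```r
db <- sensor_db("redox")
grid <- value_grid("redox", -450, -100, 0.1)

optimal_windows(db, err, grid)[c("roGFP5", "roGFP1-R12")]
#> $roGFP5
#>      lower  upper
#> [1,]  -345 -288.8
#>
#> $`roGFP1-R12`
#>      lower  upper
#> [1,] -265.6 -236.2

coverage_gaps(db, err, 10, grid = grid)
#>       lower  upper
#> [1,] -450.0 -336.7
#> [2,] -194.3 -100.0
```

The bundled database (`inst/extdata/sensor_db_synthetic.json`) contains
*reconstructed representative* conversion factors — midpoint constants taken
from the literature, factors chosen to be plausible for each family — and is
intended for demonstration and comparison methodology, not as a reference
measurement of any physical sensor. Use `load_sensor_db()` /
`save_sensor_db()` to work with your own calibrated sensors.

A command-line interface covering the same operations ships in
`inst/cli/sensorspan` (subcommands: `sensors`, `inaccuracy`, `range`,
`compare`, `gaps`, `phase`, `spectra2params`, `optimize-bands`,
`error-interval`).

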