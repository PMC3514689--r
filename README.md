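# sfpdiam

Estimation of muscle fiber diameter and fiber-to-electrode distance from
single fiber potentials (SFPs).

Single fiber electromyography (SFEMG) records the extracellular action
potential of individual muscle fibers with a highly selective needle
electrode.  Clinically it yields fiber density and jitter, but the waveform
itself also carries information about the fiber's *diameter*: the
transmembrane current grows with the diameter squared (raising the
amplitude), and the conduction velocity grows linearly with diameter
(shrinking the duration of the negative spike).  Amplitude alone is
ambiguous, because it also falls off with the fiber-to-electrode distance —
but the *pair* (amplitude, negative-peak duration) resolves both unknowns.
`sfpdiam` is for electrophysiologists and EMG modellers who want to
quantify fiber diameter electrophysiologically, complementing muscle biopsy
morphometry.

## The model

**Forward.**  The extracellular SFP is a line-source convolution

$$V(t) = \int \varphi(t-\tau)\, i(\tau)\, d\tau, \qquad
\varphi(r,z) = \frac{1}{4\pi\sigma_r}\frac{1}{\sqrt{K r^2 + z^2}}$$

where the current source $i \propto d^2\, \partial^2 e/\partial z^2$ is the
second spatial derivative of a Rosenfalck-type intracellular action
potential $e(z) = A(\lambda z)^3 e^{-\lambda z} + B$, swept past the
electrode at the conduction velocity $v = 2.2 + 0.05\,(d-25)$ m/s ($d$ in
µm).  Two features are measured on the waveform: the peak-to-peak amplitude
$a$ (mV) and the negative-peak duration $t_z$ (ms) between the
zero-crossings bounding the main negative spike.

**Inverse.**  Over the physiological operating range ($d$ 25–90 µm, $r$
50–500 µm) the duration is well approximated by two bi-quadratic surfaces

$$t_z = F_1(\log_{10} a,\; d), \qquad t_z = F_2(\log_{10} a,\; r),$$
$$F_i(x,y) = e_{i,1} + y(e_{i,2} + y\,e_{i,3}), \qquad
e_{i,j} = c_{i,j,1} + x(c_{i,j,2} + x\,c_{i,j,3}).$$

Each surface is quadratic in $y$, so a measured $(a, t_z)$ pair is inverted
in closed form for the diameter (surface 1) and the radial distance
(surface 2).  The package ships the published 18-coefficient set and a
least-squares engine that refits both surfaces to any simulated grid.  A
nomogram of iso-amplitude and iso-duration curves in the $(d, r)$ plane
provides the equivalent graphical tool.

## Worked example

```r
library(sfpdiam)

# forward: simulate a 55 um fiber recorded at 80 um
w <- simulate_sfp(fiber_scenario(55, 80))
sfp_features(w)
#> SFP features: amplitude = 1.357 mV, negative-peak duration = 0.5981 ms

# inverse: estimate geometry from the measured feature pair
m <- published_coefficients()
solve_diameter(m, 1.357, 0.593)
#> diameter_um = 55.68 um (roots 55.68 / 236.1, discriminant 2.08e-05)
solve_radius(m, 1.357, 0.593)
#> radial_um = 80.87 um (roots 80.87 / 588.9, discriminant 3.63e-06)

# how robust is the estimate to measurement error?
sensitivity(m, 1.357, 0.593)
#> Sensitivity at a = 1.357 mV, tz = 0.593 ms (d = 55.68 um, r = 80.87 um)
#>   max |delta d|: 0.256 um (amplitude), 9.25 um (duration)
#>   max |delta r|: 1.66 um (amplitude), 21.9 um (duration)
```

The inversion recovers the simulated geometry to within a micrometer for
the diameter.  The sensitivity analysis shows the estimate is far more
sensitive to duration error (one 25 kHz sample, ±0.04 ms, moves the
diameter by ~9 µm) than to amplitude error (±20 µV moves it by <0.3 µm) —
good time resolution and a low-noise baseline are what matter.

## Command line

```sh
SFPTOOL=$(Rscript -e 'cat(system.file("cli", "sfptool", package = "sfpdiam"))')
$SFPTOOL simulate --d-um 55 --r-um 80 --out-prefix out/sim
$SFPTOOL invert --published --a-mv 1.357 --tz-ms 0.593 --out out/inv.csv
$SFPTOOL fit --out out/model.json
$SFPTOOL nomogram --out-csv out/curves.csv --out-png out/nomogram.png
$SFPTOOL report --out out/report.json
```

Subcommands: `simulate`, `measure`, `fit`, `invert`, `nomogram`, `report`;
all accept `--config constants.yaml` and write provenance (constants,
package version) into their outputs.

## Package layout

- `R/constants.R`, `R/forward.R`, `R/waveform.R` — physical constants,
  line-source simulator, waveform container and CSV/JSON I/O
- `R/features.R` — amplitude and negative-peak duration extraction
- `R/inversion.R`, `R/fit.R` — bi-quadratic surfaces, published
  coefficients, closed-form solvers, sensitivity, least-squares refit,
  round-trip error reports
- `R/nomogram.R` — iso-curve families and their intersection
- `R/cli.R`, `inst/cli/sfptool` — command-line interface
- `vignettes/diameter-estimation.Rmd` — methods and design notes
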