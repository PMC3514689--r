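---
title: "Estimating muscle fiber diameter from single fiber potentials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating muscle fiber diameter from single fiber potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfpdiam)
```

## The physical model

A muscle fiber action potential propagates from the endplate toward the
tendon at a conduction velocity that grows linearly with fiber diameter,
`v = 2.2 + 0.05 (d - 25)` m/s with `d` in µm.  The extracellular potential
seen by a point electrode is modelled as a line source: the transmembrane
current per unit length, proportional to `d²` times the second spatial
derivative of the intracellular action potential (IAP), is convolved with
an anisotropic volume-conductor weight function

φ(r, z) = 1 / (4π σ_r √(K r² + z²)),

where `r` is the radial electrode distance, `z` the axial offset, `σ_r`
the radial conductivity and `K` the anisotropy factor set by the ratio of
axial to radial conductivity.  The IAP is the Rosenfalck waveform
`e(z) = A (λz)³ e^{-λz} + B`; writing it in terms of `λz` keeps the
depolarization amplitude (≈129 mV from rest to peak, with `A = 96` mV and
`B = -90` mV) independent of the axial scale `λ`.

Assumptions inherited from this model class:

* the fiber is effectively infinite — endplate and tendon end-effects are
  not modelled, so the simulated waveform is purely the propagating
  triphasic spike;
* the electrode is an ideal point; cannula and surface geometry are
  ignored;
* the source profile is fixed in the axial coordinate, so diameter enters
  the waveform *shape* only through the velocity.  The waveform in time is
  an exact `1/v` stretch of a fixed spatial profile — a property the test
  suite verifies and exploits.

## Choice of the model constants

The volume-conductor and source constants are not all identifiable from
first principles, and published values for this electrode/model
combination vary.  The package fixes them once, as follows:

* **σ_r = 0.1 S/m** — a standard radial conductivity for skeletal muscle.
  Only the product `current_scale / σ_r` affects amplitudes, so this is a
  bookkeeping choice.
* **K = 5** and **λ = 1.8 mm⁻¹** — calibrated jointly so that the
  simulated negative-peak duration spans 0.4–1.4 ms across the reference
  operating range (diameters 25–90 µm at distances 50–500 µm): the fast,
  near corner (90 µm, 50 µm) gives ≈0.40 ms and the slow, far corner
  (25 µm, 500 µm) gives ≈1.40 ms.  `K = 5` is simultaneously the standard
  axial-to-radial conductivity ratio for muscle.  Note that the canonical
  axial scale `λ = 1 mm⁻¹` is *not* compatible with this duration range
  (it yields ≈0.66–1.94 ms); the compressed depolarization zone is what
  the reference durations imply.
* **current_scale = 6.10979e-07** — calibrated so that the scenario
  (55 µm, 80 µm) yields a peak-to-peak amplitude of exactly 1.357 mV at
  the default sampling step.  `calibrate_current_scale()` re-derives it
  for any other constants.

With these constants the simulated duration at (55 µm, 80 µm) is
0.598 ms — a genuine prediction, not a calibration target — and the
grid-wide amplitude range is ≈0.03–5.1 mV, matching the expected
0.05–5 mV operating band of the method.

## Numerics of the simulator

The convolution is evaluated in the axial domain on a grid with spacing
`h = v · dt`, so that the output is uniformly sampled in time at `dt`
(default 0.002 ms, i.e. 500 kHz).  The weight function is truncated at
±50 mm, where the balanced (zero-integral) source makes the discarded
tails negligible; the source support is truncated at `30/λ` mm, where the
exponential has decayed to ~1e-9 of its scale.  The FFT-based open
convolution is exact for the discretized integrand.  Halving `dt` changes
the amplitude by <0.1 % and the duration by <0.004 ms (tested), an order
of magnitude below the 0.04 ms granularity of 25 kHz clinical sampling; a
`decimate_waveform()` export reproduces that clinical rate.  If fewer
than 10 samples span the negative peak the simulator refuses to measure
(resolution error) rather than return a quantized duration.

Time zero is placed at the instant the center of the source's
depolarization zone passes the electrode's axial position; all reported
latencies are therefore relative, and the features are invariant to time
shifts.

## Feature extraction

The amplitude is `max - min` of the samples.  The negative-peak duration
is the time between the zero-crossing entering and the zero-crossing
leaving the negative lobe that contains the global minimum, each located
by linear interpolation between the bracketing samples.  Zero volts is
the baseline: simulated waveforms are baseline-clean by construction, and
for imported recordings an optional mean-of-leading-samples correction
(default: first 10 % of samples) can be switched on.  For polyphasic
waveforms — more than two crossings — the lobe containing the global
minimum is used (ties broken toward the earlier lobe by the ordering of
crossings) and the result is flagged `polyphasic`; this convention is the
package's own, since the model class only produces triphasic shapes.

## The bi-quadratic inversion

The fitted surfaces are `tz = F_i(log10(a), y)` with the nested-quadratic
parameterization described in the README; amplitudes are in mV *inside
the logarithm* (the worked example's printed `log10(1.357) = 0.13258`
fixes the unit, and the CLI only accepts µV with an explicit flag).  The
published 18-coefficient set is bundled both in code and as a plain-text
JSON file.

Solving `F_i(x, y) = tz` for `y` is a quadratic with closed-form roots.
Root selection: the unique root inside the admissible range is taken; the
admissible range is the nominal fitted range (25–90 µm or 50–500 µm)
widened by a 40 µm margin on each side, because the reference fit is
known to behave sensibly somewhat beyond its grid and a hard wall at the
grid edge would make boundary scenarios unusable.  If both roots are
admissible the one nearer the nominal midpoint is chosen and the result
is flagged *ambiguous*; if none is, the error names both roots.  A
degenerate quadratic (vanishing leading coefficient) falls back to the
linear solution.  Every accepted root re-substitutes into the surface to
within 1e-9 ms (tested).

One genuine limitation surfaces here: the `F_2` surface is quadratic in
`r` and can *fold* — at fixed `(a, tz)` both branches may be
physiological (the vertex lies near `r ≈ 370` µm at low amplitudes).  In
real data amplitude and distance are strongly coupled, so the wrong
branch is rarely selected, but the ambiguity flag should be honored by
downstream users.

The refit engine solves the two 9-term linear least-squares systems
(monomials `x^p y^q`, `p, q ∈ {0,1,2}`) by QR decomposition with the
log-amplitude centered for conditioning and the shift folded back into
the returned coefficients, so stored coefficients are always in raw
`log10(mV)` units.  Rank deficiency (fewer than 3 distinct values on
either axis, or <9 points) is a hard error.  Mean-absolute and RMS `tz`
residuals are stored in the model.

On the default 266-scenario grid (diameters 25–90 µm step 5, distances
50–500 µm step 25) the refit residuals are ≈4e-3 ms per surface and the
round-trip (simulate → measure → invert) errors are ≈1.2 µm RMS for
diameter and ≈6.5 µm RMS for distance — these are recomputed, not quoted,
by `scripts/acceptance.R` and the test suite.  A handful of far-corner
scenarios (90 µm diameter at distances ≥350 µm) have no admissible root
under the refit surfaces; they are reported as flagged rows, consistent
with the largest approximation errors sitting at the edge of the
interpolation region.

## Sensitivity analysis

`sensitivity()` re-solves the inversion at the four signed single-axis
perturbations of the base point, by default ±20 µV in amplitude and
±0.04 ms in duration (one sample at 25 kHz).  At the worked-example base
point the diameter moves <0.3 µm under the amplitude perturbation and
≈9 µm under the duration perturbation; the asymmetry — duration error
dominating amplitude error — holds across the operating range (tested as
a property).  The practical reading: diameter estimation requires
good time resolution and a quiet baseline (<20 µV noise) far more than
accurate gain.

## The nomogram

`iso_duration_curve()` and `iso_amplitude_curve()` trace the two curve
families in the `(d, r)` plane.  The default source is the forward
simulator (ground truth): for each diameter on a 1 µm grid the radial
profile of the feature is monotone, so the level is bracketed and found
by `uniroot` to 0.1 µm.  A fitted or published model can be used instead,
in which case the curve is generated parametrically (sweep one feature,
solve both quadratics); where the sweep leaves the fit's data support a
quadratic branch can fold back, so the implementation keeps the longest
run of sweep steps along which diameter and distance move together — the
physical branch.

For the feature pair (0.7 mV, 0.6 ms) the published coefficients place
the solution at ≈(68.9 µm, 166.9 µm), while the package's own
simulator-sourced curves intersect at ≈(62 µm, 194 µm).  The radial
coordinate of this low-amplitude intersection is the one quantity where
the package's calibrated volume conductor visibly deviates from the
reference model: the two printed duration-range anchors and the single
amplitude anchor pin the calibration near the worked example but leave
the amplitude-versus-distance decay at low amplitudes under-determined.
The corresponding acceptance check is deliberately left failing rather
than widened; users comparing against the reference graphical tool should
expect radial estimates at low amplitude to differ by some tens of µm
between the two models, and should prefer the analytic inversion (whose
round-trip accuracy is tested) over graphical reading in that region.

## What the synthetic generator does and does not emulate

The simulator produces clean, noise-free, baseline-true, strictly
triphasic single-fiber potentials from an idealized point electrode.  It
does not emulate: additive recording noise, baseline drift, jitter,
superimposed potentials from neighboring fibers, finite fiber length,
electrode shaft effects, or pathological polyphasic shapes.  Passing
tests therefore demonstrate the correctness and internal consistency of
the method under its own model class — not its clinical accuracy.  The
feature extractor's noise-oriented affordances (baseline correction, the
20 µV noise warning in the CLI) are provided for imported recordings but
are exercised only on synthetic fixtures.

## Problem sizes

The test suite and acceptance script use the full 266-scenario reference
grid at the default 0.002 ms sampling for round-trip and monotonicity
checks, 36-scenario grids for refit unit tests, and coarser diameter
grids (2–5 µm steps) for simulator-sourced nomogram checks; these sizes
keep every individual check well-resolved while the whole suite completes
in a few minutes on one CPU.
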