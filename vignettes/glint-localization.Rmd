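---
title: "Localization entropy from glint-sampled binaural amplitude cues"
author: "glintloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localization entropy from glint-sampled binaural amplitude cues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glintloc)
```

## The question the model answers

Constant-frequency echolocators cannot use spectral cues to localize
echoes.  Instead they sweep their pinnae during echo reception, so the
combined emission-plus-ear directionality (the augmented HRTF) imprints a
direction-specific amplitude modulation on the echo at each ear.  A
fluttering insect additionally produces one amplitude-stable, strongly
Doppler-shifted *dominant glint* per wingbeat.  A bat that reads the
modulation only at the dominant-glint times trades bandwidth for noise:
it keeps the most amplitude-stable parts of the echo (low measurement
noise) but receives only `flutter rate x call duration` samples per ear —
between 1 and 10 for 20–200 Hz flutter in a 50 ms call.

`glintloc` treats localization as an ideal-observer template-matching
problem and asks: how much direction information, measured as the
Shannon entropy of the posterior over a discrete direction grid, survives
this sampling at a given flutter rate, echo strength and noise level?

## Model components and assumptions

**Direction grid.**  Candidate directions are distributed near-uniformly
(equal-area) over the frontal hemisphere with a deterministic golden-angle
spiral in the cosine of the off-axis angle; the construction is exact in
the requested count and reproducible.  The reference configuration uses
3252 directions (chance level `log2(3252)` = 11.7 bits); the desk-scale
default is 500.  All spatial maps use the Lambert azimuthal equal-area
projection centred on the midline.

**Directivity.**  The synthetic stand-in for measured or simulated beam
patterns is a circularly symmetric Gaussian lobe in off-axis angle,
peak-normalized to 0 dB, parametrized by its full half-power beamwidth
(gain is −3 dB at half the beamwidth off boresight), with an optional
raised-cosine side lobe of configurable level and offset.  Defaults:
emission 40° beamwidth on the midline; ears 45° beamwidth with boresights
at ±20° azimuth, +10° elevation, so the two ears carry genuine binaural
disparity.  Measured/simulated grids can be loaded from CSV
(`azimuth_deg, elevation_deg, gain_db` on a complete lattice) and are
evaluated by bilinear interpolation after peak re-normalization.

**Pinna motion.**  Each ear sweeps a rigid-rotation arc of ±15° in both
azimuth and elevation (about 30° total, oblique), the right ear rising in
elevation while the left descends; the emission pattern stays fixed.
Rigid rotation of the ear pattern is the standard approximation for small
pinna movements; pinna deformation is not modelled.  Because the
literature's azimuth sign convention for the two ears is ambiguous, both
pairings are available (`az_convention = "mirrored"` or `"parallel"`).

**Templates.**  For each direction, the expected received level at each
ear and stroke position is emission gain plus rotated ear gain; each
template is then normalized to zero mean over all `2 * n_pos` entries.
Zero-mean normalization makes the echo strength `A` the sole carrier of
absolute level, which is what lets it act as a clean nuisance parameter;
adding any constant to all directivity gains provably leaves templates
unchanged.  One full ear stroke is assumed to span exactly one call
duration, and glint times map linearly onto fractional stroke positions
with linear interpolation in dB between positions (at the default
resolution the interpolation choice is immaterial).

**Stroke positions (`n_pos = 40`).**  This is not a pure discretization
knob: in the whole-echo channel the noise covariance has dimension
`2 * n_pos`, so `n_pos` sets how many *independent* amplitude
measurements a channel that listens for the entire echo is credited
with.  If positions were spaced arbitrarily finely, that channel's
information would grow without bound — an artefact, since real amplitude
interference decorrelates on a finite time scale.  The default of 40
positions spaces samples 1.25 ms apart over the 50 ms call, about the
shortest fluctuation time scale the noise model treats as independent,
while still representing template modulations up to 20 cycles per
stroke.  It is configurable for sensitivity analyses.

**Glint schedules.**  Regular mode places samples exactly one flutter
period apart with the first drawn uniformly in half a period, giving
exactly `f x D` samples for the rates of interest; random mode keeps that
count but draws the times uniformly over the call, which is the
like-for-like comparison used to test sensitivity to irregular wingbeats.

**Noise.**  Received levels are in dB.  Noise is Gaussian, i.i.d. across
glint times, with correlation `rho_lr = 0.9` between simultaneous
left/right samples (they share one echo, so they are highly but not
perfectly correlated); all other covariances are zero.  Three reference
channels are used: `sigma = 1.5` dB for the amplitude-stable dominant
glints, `6` dB for channels driven by the whole echo, and `3` dB in
between.  The detection floor at 0 dB acts as an elementwise maximum on
the expected level, so `A` is interpretable as SNR.  These constants are
package defaults standing in for ensonification-measurement values, and
every one of them is configurable.

**Inference.**  The likelihood is a multivariate Gaussian about the
floor-censored mean `max(0, T + A)` — censoring enters through the mean,
not through a Tobit-style censored density, matching the structure of the
measurement model above.  Echo strength is marginalized by a uniform
discrete sum over the strength grid (0–70 dB in the reference
configuration), computed with log-sum-exp throughout; an exact censored
likelihood is a possible extension.  The posterior uses a uniform
direction prior, and entropy uses the `0 log 0 = 0` convention.

## Monte-Carlo estimation

Mean entropy per (direction, flutter rate, strength) cell is averaged
over 20 realizations of the schedule phase and the noise (10 in
scaled-down property checks).  The glint phase is redrawn per realization
by default (configurable), since a hovering bat would face a fresh
phase on every call.  `entropy_surface()` vectorizes the computation:
within one realization, all source directions and strengths share the
drawn schedule, so likelihood evaluation reduces to dense matrix products
against a whitened template bank (the block covariance whitens in closed
form pair by pair).  Sharing the schedule across cells within one
realization leaves every per-cell mean unbiased; the slow per-cell
reference path (`average_entropy()`) is retained and the test suite
checks the two routes against each other.  All randomness flows from one
root seed through deterministically derived per-stream seeds, so any cell
is reproducible in isolation and full runs are bit-identical.

A note on noise-free runs: with `sigma = 0` the posterior degenerates to
uniform mass over exact template matches.  The squared distances are
computed via an inner-product expansion whose cancellation error scales
with the squared norms, so the match tolerance is row-relative rather
than absolute.

## Experiment drivers and problem sizes

The drivers mirror the study's figure-level analyses at configurable
scale: entropy maps per flutter rate, the flutter sweep with
baseline (200 Hz) differences in regular and random modes, the
dominant-glint versus whole-echo channel comparison (the latter uses the
full templates with the covariance extended to `2 * n_pos` and is
flutter-independent), template diagnostics (dynamic range, modulation
spectrum with an energy-preserving one-sided convention, Nyquist limits
`f x D / 2`), and trade-off maps of entropy versus echo strength for two
noise channels with a central-versus-peripheral contrast (central =
within 30° of the midline, configurable).

Default problem sizes are desk-scale choices: a 500-direction grid, five
flutter rates, eight strengths (0–70 dB in 10 dB steps) and 20
realizations per cell; property checks in the test suite use 300
directions and 10 realizations, sizes at which all the qualitative
orderings reported here are stable.  The reference scale (3252
directions, 5 dB strength steps) is available through the configuration
and the CLI's `--full` flag.

## What the synthetic generator does and does not emulate

The parametric beams reproduce the features that drive the cue structure:
smooth single-lobed directionality at ~75 kHz scale, lateralized ear
boresights, anti-phase oblique pinna arcs, and optional side lobes.  They
do not reproduce the fine structure of a real bat head's directionality —
multi-lobed interference patterns, frequency dependence, or left/right
asymmetries.  Consequently, passing tests demonstrate the *information
budget* of glint-sampled amplitude-modulation cues under the stated noise
model, and the orderings among conditions; they do not certify absolute
entropy levels, crossover flutter rates, or map shapes for any real
species.  Those quantities require measured or simulated directivity
grids, which `load_directivity()` accepts in place of the synthetic
beams.

## Numerical and design choices

- Geometry is done on 3-D unit vectors (forward/right/up); azimuth
  rotations compose before elevation rotations so that the forward
  direction maps exactly onto the commanded offset.  This avoids polar
  artefacts at the hemisphere rim.
- The equal-area grid is deterministic; nearest-neighbour spacing has a
  coefficient of variation under 0.25 (about 0.03 in practice).
- Likelihood aggregation uses log-sum-exp; posteriors that underflow
  entirely (all `-Inf`) fall back to uniform with a warning.
- CSV output formats doubles with 17 significant digits, making
  write/read round-trips exact.
- Degenerate inputs: single-direction grids, single-position strokes and
  single-sample schedules are all defined and tested; empty schedules,
  non-positive rates/widths, and singular covariances (`rho = 1`) are
  rejected with named errors.

## Known limitations

- The censored-mean Gaussian likelihood is an approximation near the
  detection floor; a Tobit-style likelihood would treat clipped samples
  exactly.
- Noise is white across glint times; temporally correlated interference
  (e.g. slowly varying clutter) is subsumed into the per-sample sigma.
- The model scores ambiguity (entropy), not point-estimate accuracy; no
  error-angle statistics are produced.
- Head and target are static during a call; multi-call integration and
  tracking are out of scope.
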