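---
title: "Methods: DPIV analysis of acousto-mechanically modulated microchannel flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DPIV analysis of acousto-mechanically modulated microchannel flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acoustopiv)
```

## Overview

`acoustopiv` measures how suspended micro-particles in a microchannel
respond to a periodic acousto-mechanical stimulus. The measurement
chain is: grayscale video → multi-pass DPIV velocity fields → spatially
averaged velocity traces → time-domain (velocity range) and
frequency-domain (dominant peak, band integrals) response metrics →
replicate aggregation. A synthetic particle-video generator provides
ground-truth input for every stage, since the recordings the analysis
was designed around are not publicly deposited.

This vignette documents the model assumptions, the tunable parameters,
the numerical choices, and the limits of what the synthetic validation
can show.

## The stimulation protocol

A `stimulus_protocol` is an ON–OFF schedule: `on_s` seconds of carrier
tone followed by `off_s` seconds of rest, repeated over `total_s`
seconds. Defaults are 1 s / 1 s over 60 s, giving a 2 s modulation
period and a 0.5 Hz fundamental — the line expected to dominate the
low-frequency velocity spectrum of a responding suspension. The
schedule starts ON at t = 0 and phase boundaries belong to the phase
they open (half-open intervals); whether a real recording starts
synchronized with an ON onset is an assumption, but only the period,
not the phase, determines the spectral line position.

Carrier tones are specified in scientific pitch notation under
twelve-tone equal temperament (`note_frequency()`, A4 = 440 Hz). The
two standard tones are exposed as `AMP_LOW` (G♯0, ≈ 25.96 Hz) and
`AMP_HIGH` (G♯4, ≈ 415.30 Hz). Scientific notation is used exclusively
because informal octave labels ("first octave", "fourth octave") do not
map to a single consistent numbering; the presets pin down the two
frequencies unambiguously.

## Synthetic data generator

### What it emulates

`simulate_trajectories()` advances particles through a superposition of

- steady transport: a blunt parabolic (Poiseuille-like) profile across
  the channel width, normalized to 1 at the centerline, scaled by the
  cross-section-averaged velocity `Q/(w·d)`. The channel depth is not
  optically resolved, so a square 0.40 × 0.40 mm cross-section is
  assumed — this keeps simulated speeds in the 0.01–0.5 mm/s regime
  that a 57 FPS camera with 0.74 µm object-plane pixels can track;
- a stimulus-gated longitudinal velocity boost (the bulk flow increase
  during ON phases that a flow sensor at the outlet would register);
- stimulus-gated in-band carrier oscillations (default lines at 12, 19
  and 25 Hz) in the flow-parallel direction and, for compliant
  particles, also transversely;
- isotropic positional jitter (default 0.05 px/frame) so interrogation
  windows never see perfectly static texture.

The stimulus terms are shaped by an envelope — linear ramp over
`rise_s` (default 0.3 s) after an ON onset, exponential decay with
`decay_tau_s` (default 0.3 s) after OFF — emulating the delayed onset
and gradual relaxation visible in stimulated recordings, and scaled by

\[ s = (Q/Q_{\mathrm{ref}})^{\alpha} \, d^{\beta}, \qquad
   d = (f_{\mathrm{tone}}/f_{G\sharp0})^{0.21} , \]

where \(\alpha\) (`coupling_flow_exponent`) and \(\beta\)
(`coupling_drive_exponent`) are particle properties and \(d\) is the
drive strength of the tone. The exponent 0.21 makes the G♯4 tone about
1.8× stronger than G♯0, reflecting the stronger actuator–tubing
coupling observed at the higher excitation frequency in calibration
measurements. The two presets encode the intended contrast:

| parameter | `silica_bead_particle()` | `yeast_particle()` |
|---|---|---|
| radius, density | 3.0 µm, 1200 kg/m³ | 2.5 µm, 1126 kg/m³ |
| longitudinal boost (mm/s) | 0.12 | 0.022 |
| transverse gain | 0 | 0.6 |
| flow exponent α | 0 | 0.45 |
| drive exponent β | 0 | 1 |

Beads therefore respond identically at every flow rate and octave and
show no transverse component; yeast-like particles respond more
strongly at higher flow rates and under the higher tone, with
transverse carrier lines co-located with the longitudinal ones. The
boost and line amplitudes were chosen once so that the resulting
velocity ranges fall in the 0.03–0.4 mm/s decade of the experimental
regime; no absolute amplitude is claimed, since the mechanical
excitation amplitude delivered to a real channel is not known.

The 415.30 Hz carrier itself exceeds the 28.5 Hz Nyquist limit of a
57 FPS camera, so the generator injects in-band (10–28 Hz) lines
directly rather than modelling aliasing physics — only in-band
signatures are observable, and only those are analyzed.

`render_frames()` draws each particle as an isotropic Gaussian spot
(default σ = 1.2 px, peak 160 grey levels on a background of 20) with
additive Gaussian read noise (σ = 3), quantized to 8 bit. Particles
leaving the ROI re-enter at the opposite edge, keeping seeding density
constant (default 80 particles in the 180 × 140 px ROI).
`simulate_flow_sensor()` produces the matching calibration traces: a
first-order response that rises during ON and relaxes with a
configurable time constant during OFF, plus an optional slowly
accumulating persistent offset for the strong-drive regime where the
signal never returns to baseline within an OFF phase.

### What it does not emulate

No acoustic radiation forces, standing waves, particle–particle or
particle–wall interactions, sedimentation, out-of-plane motion,
illumination drift, or motion blur. Passing tests therefore demonstrate
that the *pipeline* recovers known kinematics from realistic images;
they do not validate any physical model of acoustofluidic coupling.
Likewise the generator makes the bead in-band response flow-invariant
by construction, so flow-dependent trends in bead band integrals are
outside what the synthetic campaign can probe.

## DPIV engine

### Interrogation scheme

`multipass_piv()` uses three passes with 64 → 32 → 16 px windows at
50 % overlap (configurable via `piv_config()`). Window sizes, overlap,
sub-pixel estimator and validation are not prescribed by the analysis
this package implements — they follow PIV community practice. The
"three-step" refinement interpretation (halving window size per pass)
is adopted; a fixed-size window-offset variant is available by passing
equal-power-of-two `window_sizes` of your choice.

Each pass correlates mean-subtracted windows by circular FFT
cross-correlation. Subsequent passes pre-shift the windows of the
second frame by the rounded displacement interpolated (bilinearly) from
the previous validated pass, so the residual displacement entering the
final 16 px pass is at most a pixel or so. Circular (rather than
zero-padded linear) correlation is a deliberate dialect choice: with
window offsetting the residuals are far below the window size, where
the two are equivalent and the circular form is cheaper.

### Sub-pixel estimation and window weighting

The integer peak is refined per axis with the three-point Gaussian fit
\(\delta = (\ln c_- - \ln c_+)/(2\ln c_- - 4\ln c_0 + 2\ln c_+)\),
which is exact for a sampled Gaussian correlation peak; when any of the
three samples is non-positive the parabolic fit is used instead. A peak
on the correlation-plane border cannot be refined and invalidates the
vector.

Particle images truncated by the window border systematically bias the
sub-pixel estimate towards integer displacements (they correlate
edge-to-edge at zero lag). The interrogation windows are therefore
weighted with a Gaussian taper (σ = window/4) after mean subtraction,
which in the rigid-translation benchmarks reduces the worst-case median
bias from ≈ 0.17 px to below 0.05 px at the default spot size. The
taper can be disabled (`weighting = "none"`), which recovers the
textbook unweighted correlation at the cost of that bias.

### Validation and conversion

Vectors are screened with the normalized-median test on the
8-neighborhood: residual = |v − median| / (MAD + 0.1 px) per component,
flagged above threshold 2.0 (configurable; ∞ disables). Flagged and
degenerate (featureless) windows are replaced by the local mean of
valid neighbors during intermediate passes — the offset field must be
smooth — and optionally in the final output; they stay marked invalid
either way and are excluded from spatial averages. Grids smaller than
3 × 3 skip validation with a warning.

Displacements convert to physical velocity as
`v [mm/s] = d [px] · (sensor_pixel/magnification) · 10⁻³ · frame_rate`;
defaults (7.4 µm sensor pixel, 10× objective, 57 FPS) give
0.04218 mm/s per pixel-per-frame. Frames are paired consecutively, so
velocity traces are sampled at the frame rate and spectra extend to the
28.5 Hz Nyquist limit. Image convention: x is flow-parallel
(horizontal), y is transverse with downwards positive; transverse
metrics use spectra, so the sign convention does not affect results.

## Metrics

- **Velocity range** `r = max − min` of the spatially averaged trace.
  Frame pairs with no valid vector are linearly interpolated from
  neighbors (and counted) rather than dropped, preserving uniform
  sampling for the DFT.
- **Amplitude spectrum**: mean removed, one-sided `2|DFT|/N` (Nyquist
  bin not doubled), DC reported as 0. No taper by default: a recording
  spanning an integer number of protocol periods puts the modulation
  line exactly on a bin, where the rectangular window is leak-free. A
  Hann option exists for protocols whose period does not divide the
  record length. The spectrum's normalization is a package convention
  (mm/s per bin); published bar-plot scales based on unstated
  normalizations are not reproduced numerically, only their trends.
- **Dominant peak**: maximum amplitude over the bins in the requested
  band (default 0–2 Hz) excluding DC — with the flow-driven DC term
  removed, the 0.5 Hz protocol line is the expected maximum for a
  responding suspension. Ties break towards the lower frequency.
- **Band integrals** over half-open bins `f₁ ≤ f < f₂` (presets
  10–15, 18–23, 23–28 Hz), so touching bands never double-count an edge
  bin and adjacent integrals add exactly.
- **Replicates**: mean and SEM = sd/√n (sample sd, n − 1 denominator).
- **Calibration**: ON/OFF phase means, their difference (modulation
  amplitude), and the late-OFF plateau (final 20 % of each OFF phase)
  relative to a baseline. Since the schedule opens ON there is no
  pre-stimulation segment; the first OFF plateau serves as the default
  baseline, or one can be supplied.

## Campaign orchestration

`campaign_plan()` builds the standard condition matrix — beads at
{0.0001, 0.001} mL/min, yeast at {0.0001, 0.001, 0.005} mL/min, each as
unstimulated control plus both tones — and `run_plan()` executes every
condition × replicate with deterministic per-run seeds, records
failures without aborting the campaign, and emits a manifest
(seeds, configuration checksum, package version) sufficient to
reproduce the results table bit-for-bit.

## Problem sizes and determinism

The package's own validation uses 20 s recordings (1140 frames,
80 particles, three seeds per condition) for the campaign-level trend
checks and a single 60 s recording (3420 frames) for the
protocol-peak recovery check; at these sizes a full campaign runs in
minutes on one CPU. Longer recordings sharpen the spectral resolution
(1/duration Hz) but change nothing structurally. All randomness flows
from explicit seeds; identical seeds reproduce trajectories, frames,
sensor traces and result tables exactly.

## Known limitations

- Correlation-based DPIV measures the motion of the particle-image
  pattern; at very low seeding density individual windows are
  featureless and rely on validation plus interpolation.
- The sub-pixel estimator retains a small (< 0.05 px median)
  peak-locking residual; velocity differences below ~2 × 10⁻³ mm/s per
  frame pair are not resolvable at the default calibration.
- The synthetic generator's amplitude scale is conventional, so only
  relative contrasts (bead vs yeast, across flow rates and tones) carry
  meaning, not absolute agreement with any particular experiment.
- Ensemble correlation, window deformation, 3-D/stereo PIV and particle
  tracking are out of scope.
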