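# acoustopiv

Digital particle image velocimetry (DPIV) analysis of micro-particle
videos recorded in microfluidic channels under ON–OFF acousto-mechanical
stimulation, plus a synthetic particle-video generator for end-to-end
validation.

## The problem

Suspended micro-particles (rigid silica beads, compliant yeast cells)
flowing through a microchannel can be perturbed by acoustic tones
mechanically coupled into the tubing. The analysis question is whether —
and how strongly — the particles respond to a periodic stimulation
protocol (1 s of tone ON, 1 s OFF, repeated over a 60 s recording), and
whether the response separates rigid from compliant particles.

The pipeline answers this from raw grayscale video alone:

1. **DPIV** — multi-pass FFT cross-correlation (64 → 32 → 16 px
   interrogation windows, 50 % overlap) with three-point Gaussian
   sub-pixel peak fitting and normalized-median vector validation turns
   consecutive frame pairs into velocity fields
   `v [mm/s] = d [px] · (pixel pitch) · (frame rate)`.
2. **Spatial averaging** — valid vectors are averaged per frame pair
   into traces V̄ₓ(t) (flow-parallel) and V̄ᵧ(t) (transverse), sampled
   at the camera frame rate (57 Hz by default).
3. **Response metrics** —
   - velocity range `r = max V̄ᵢ(t) − min V̄ᵢ(t)`;
   - one-sided amplitude spectrum V̄ᵢ(f) (mean removed, 2|DFT|/N);
   - dominant non-DC peak `fp = max V̄ᵢ(f)` in a low-frequency band
     (default 0–2 Hz, where the 2 s protocol period puts its 0.5 Hz
     fundamental);
   - band integrals `A[f₁,f₂) = Σ V̄ₓ(f)` over the 10–15, 18–23 and
     23–28 Hz presets;
   - replicate aggregation as mean ± SEM (`sd/√n`, n = 3).

Because the original videos are not public, the package ships a
first-class synthetic generator (`simulate_trajectories()`,
`render_frames()`) that emulates the acquisition (57 FPS, 7.4 µm sensor
pixels, 10× objective, 180 × 140 px ROI) and the two particle
behaviors: beads respond stably and only longitudinally, yeast-like
cells respond with flow-rate- and tone-dependent gain and a transverse
component. Every stage of the pipeline is tested against this generator
and against closed-form oracles.

## Worked example

Simulate one stimulated yeast condition (20 s at 57 FPS, 80 particles),
run the full image → DPIV → metrics chain, and inspect the response:

```r
library(acoustopiv)

res <- run_condition("yeast", flow_rate = 0.001, mode = "amp-low",
                     duration_s = 20, seed = 42, keep_traces = TRUE)
print(res$summary[, c("component", "r_mm_s", "fp_amplitude", "fp_frequency_hz",
                      "A_10_15", "A_18_23", "A_23_28")], digits = 3)
#>   component r_mm_s fp_amplitude fp_frequency_hz A_10_15 A_18_23 A_23_28
#> 1         x 0.1031     0.031843             0.5  0.0610  0.0456  0.0415
#> 2         y 0.0525     0.000192             0.5  0.0317  0.0243  0.0217

pk <- dominant_peak(res$spectra$x, band = c(0, 2))
cat(sprintf("dominant longitudinal peak: %.4f mm/s at %.3f Hz\n",
            pk$amplitude, pk$frequency_hz))
#> dominant longitudinal peak: 0.0318 mm/s at 0.500 Hz
```

The longitudinal velocity range (`r_mm_s` ≈ 0.10 mm/s) and the dominant
spectral peak locked to the 0.5 Hz protocol fundamental are the primary
readouts; the `A_*` columns quantify the higher-frequency (10–28 Hz)
carrier signature, which for yeast-like particles also appears in the
transverse component. An unstimulated control (`mode = "no-amp"`) shows
no 0.5 Hz line.

`campaign_plan()` + `run_plan()` execute the full condition matrix
(beads at 2 flow rates, yeast at 3, each as control and under the G♯0 /
G♯4 tones, n = 3 replicates) and aggregate every metric to mean ± SEM;
`report()` prints the summary table.

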