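# radarvitals

Contactless monitoring of respiration, sleep pose and body movement
with a simulated stepped-frequency continuous-wave (SFCW) MIMO imaging
radar — the full chain from raw-data physics to vital-sign estimates,
in R.

## What it does and for whom

A millimetre-wave MIMO radar beside a bed can image a sleeping person
in 3D (range × azimuth × elevation) and track sub-millimetre skin
displacement through the phase of the reflected signal. This package
is for researchers in biomedical radar and contactless monitoring who
want a reproducible, fully synthetic test bench for that processing
chain:

* **Scene simulation** — a breathing person as a time-varying
  point-scatterer scene (three pose classes, six labelled torso
  joints, scripted breathing rate/amplitude/phase offset, limb
  movements, antiphase "paradoxical breathing" episodes, clutter),
  plus the exact bistatic SFCW received-signal model
  `s(t,f,x_t,z_t,x_r,z_r) = Σ w·exp(−j k_f (R_t+R_r)) / (16π² R_t R_r)`.
* **Imaging** — the spatially matched filter
  `I(t,r,φ,ϑ) = (LMN)^{-1} Σ w s exp(+j 4π/c₀ (ℓ−L/2)Δf r)·
  exp(−j k₀[(m−1)d_rx u + (n−1)d_tx v])` with `u = cosϑ sinφ`,
  `v = sinϑ`, evaluated by a zero-padded 3D FFT and validated against
  the direct triple sum.
* **Reduction & indicators** — 25 s windows reduced to
  `I(t, r_jMA, φ, ϑ)` and `rMA(t, φ, ϑ)`; five per-cell features
  (mean amplitude; mean/max normalized phase-spectrum magnitude in the
  0.09–0.70 Hz respiration band; std and 95th percentile of `rMA`).
* **Detection** — presence (cell-count threshold on `α₁`) and limb
  movement (phase steps > 1.5 rad, 0.5 s smoothing, 5 s intervals).
* **Pose & joints** — a forked CNN on the indicator heatmaps:
  3-class sleep-pose softmax and 18-output joint regression trained
  with the mean angular loss between true and predicted
  radar-to-joint directions.
* **Respiration** — chest/abdomen partition from the joints,
  amplitude-weighted band-passed (0.05–6 Hz) phase traces, STFT
  breathing rate with harmonic summation, and the windowed
  chest–abdomen angle `Θ(t) = cos⁻¹(⟨r_a, r_c⟩ / (‖r_a‖‖r_c‖))` for
  paradoxical-breathing detection.

## Worked example

Simulate 60 s of a supine person breathing at 12 cycles/min, reduce,
detect presence and estimate the breathing rate:

```r
library(radarvitals)

cfg    <- radar_config("desk")          # reduced-size radar for studies
scene  <- make_pose_scene("supine", person_height = 1.75,
                          person_width = 0.40, seed = 1)
script <- motion_script(breathing_rate = 12, amp_chest = 0.004,
                        amp_abd = 0.006, phase_offset = 10)
rec    <- simulate_recording(scene, script, duration = 60, cfg,
                             seed = 1, snr_db = 20)

maps <- compute_indicators(rec$windows[[1]])
detect_presence(maps)
#> [1] TRUE

merged <- merge_reduced(rec$windows)
masks  <- partition_torso(scene$joints, cfg$grid)
trace  <- region_displacement(merged, masks$abdomen)
breathing_rate(trace, merged$frame_rate)
#>   time rate_cpm quality
#> 1   20       12    TRUE
#> 2   25       12    TRUE
```

The presence detector fires because dozens of cells concentrate phase
energy in the respiration band (an empty-bed scene yields zero such
cells), and the harmonic-summation estimator recovers the scripted 12
cycles/min exactly at both STFT frames. `derived_parameters(sfcw_waveform())`
prints the full-size system constants: 5.75 cm range resolution,
2.1 m unambiguous range, 22.9 mm/s maximum trackable radial velocity.

The simulation studies behind the validation suite are exported:
`study_rate_recovery()`, `study_phase_shift()`, `study_movement()`,
`generate_pose_dataset()` + `study_pose_net()`. A thin command-line
driver is installed at `inst/cli/radarvitals.R`
(`simulate | features | detect | respiration | report` over a
container directory).

## Method vignette

`vignettes/radar-vital-signs.Rmd` documents the signal model, every
algorithmic convention (normalizations, thresholds, tie-breaks), the
design decisions that were genuinely open, what the synthetic scenes
do and do not emulate, and the study problem sizes.
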