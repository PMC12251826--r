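---
title: "Contactless vital-signs monitoring with a simulated SFCW MIMO radar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless vital-signs monitoring with a simulated SFCW MIMO radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A person asleep in bed moves in ways that carry clinical information:
the chest and abdomen rise and fall with respiration, limbs move during
restless phases, and during obstructed (paradoxical) breathing the chest
and abdomen move against each other. A millimetre-wave radar beside the
bed can observe all of this without contact. A single-channel continuous
wave radar, however, receives one superposition of all reflections and
cannot tell the chest from the abdomen, or a person from an empty bed
with a moving curtain. `radarvitals` implements the full processing
chain for a *stepped-frequency continuous-wave (SFCW) MIMO imaging*
radar that can: an L-shaped array of `N` transmit elements (on the
z-axis) and `M` receive elements (on the x-axis) transmits `L` discrete
tones spanning bandwidth `B`, and every 50 ms a complete data cube
`s[t, l, m, n]` is collected from which a complex 3D image over range
and the two direction cosines is reconstructed.

The package contains both sides of a simulation study:

* a **scene simulator** producing a breathing person as a time-varying
  point-scatterer set with full ground truth, and the exact bistatic
  received-signal model
  `s = sum over scatterers of w exp(-j k_f (Rt + Rr)) / (16 pi^2 Rt Rr)`,
  with the frequency-dependent wavenumber `k_f = 2 pi f / c0` and exact
  per-element distances `Rt`, `Rr`;
* the **analysis chain**: windowed matched-filter imaging with a 3D-FFT
  fast path, reduction of each 25 s window to per-cell time series,
  five indicator features per cell, threshold detectors for presence
  and movement, a forked convolutional network for sleep-pose
  classification and torso-joint regression, and respiratory-motion
  extraction with STFT harmonic-summation rate estimation and a
  windowed chest-abdomen phase-shift angle.

Because the simulator implements the *exact* bistatic model while the
imaging assumes the far-field approximation, the analysis chain is
always exercised against the stricter physics.

## Imaging: matched filter and FFT fast path

The spatially matched filter evaluates, for each candidate range `r`
and direction cosines `u = cos(theta) sin(phi)`, `v = sin(theta)`,

```
I(t, r, phi, theta) = 1/(LMN) * sum_{n,m,l} w(l,m,n) s(t,l,m,n)
    * exp(+j 4 pi / c0 (l - L/2) df r)
    * exp(-j k0 [ (m-1) d_rx u + (n-1) d_tx v ])
```

with a separable Hanning taper `w`. The phase is linear in `(r, u, v)`,
so a zero-padded 3D FFT evaluates the filter exactly at uniform bins in
range and direction cosine; the `(phi, theta)` maps are produced by
axis labelling (`theta = asin(v)`, `phi = asin(u / cos(theta))`), never
by regridding, because interpolation would add unquantified error. A
direct triple-sum implementation (`matched_filter_direct`) serves as
the oracle: the FFT path agrees with it to better than one part in
`1e6` at bin centres.

One convention deserves a note. Evaluating the exact bistatic model for
elements on the positive axes gives a received angular phase of
`+k0 x_m u` for a scatterer at direction cosine `u`; the matched filter
therefore applies the *conjugate* angular phase so that the image peaks
at the scatterer's true direction. Expositions of the far-field model
sometimes write both signal and filter with the opposite sign, which is
the same algebra under a mirrored angle convention; the implementation
fixes the convention by validating peak positions against the exact
forward model. The arrays are centred on the origin, which keeps the
residual far-field phase error across the 4 cm aperture below about a
third of a radian at 1.5 m; the filter's `(m-1)`-indexed phase then
differs from the centred geometry only by a constant per-cell phase,
which cancels in every magnitude or phase-difference quantity.

The default grid reproduces the full-size system: a 128 x 64 x 64 FFT
cropped to 72 x 17 x 25 (range x azimuth x elevation) cells around the
bed. The cell counts alone do not determine the crop bounds uniquely;
the defaults place the 72 range bins over 0.30-1.50 m and the
angular bins symmetrically about boresight, and all bounds are
configurable.

## Reduction and indicators

Recordings are split into windows of `tau = 25 s` with a 5 s overlap.
For each window and each azimuth-elevation cell, the range bin `jMA`
with the largest time-mean amplitude is selected (ties to the smaller
index) and only `I(t, r_jMA, phi, theta)` is stored, along with the
per-frame range of maximum amplitude `rMA`; this reduces a 4D image
sequence to two thin arrays while keeping what matters: breathing lives
in the phase of the stored values (a radial skin displacement `d`
shifts the two-way phase by `4 pi d / lambda0`, 2.7 rad per mm at
65.5 GHz), gross movement lives in `rMA`. The maximum of the *complex*
image along range is implemented as the maximum of its magnitude.
Frames are reconstructed and reduced window by window, so the full 4D
sequence is never held in memory.

Five per-cell indicators summarize a window: the mean amplitude; the
mean and the maximum (`alpha1`, `alpha2`) of the normalized spectrum of
the unwrapped phase inside the respiration band 0.09-0.70 Hz; and the
standard deviation and 95th percentile (`beta1`, `beta2`) of `rMA`
(sample standard deviation; percentile by linear interpolation between
order statistics). The spectrum is normalized to unit sum over positive
frequencies with the DC bin excluded: the absolute phase offset of a
cell (about `-2 k0 r`, thousands of radians) carries no displacement
information and would otherwise swamp the normalization; with the unit
sum, `alpha1 <= alpha2 <= 1` are clean fractions and the presence
threshold below has a scale-free meaning. The spectrum uses the plain
500-sample FFT of the window with no padding or detrending beyond
unwrapping. Cells whose mean amplitude is less than 10 dB above the window's
lower-quartile amplitude (the amplitude floor, configurable;
the lower quartile tracks the background level even when bright body
cells cover much of a tightly cropped map) are considered
noise-dominated and take the minimum value of each indicator over the
passing cells. Each indicator is arranged both per azimuth-elevation
cell and, by assigning each cell's value to its `jMA` range bin and
averaging over azimuth, per elevation-distance cell.

## Detectors

**Presence.** A window contains a person when more than 10 cells have
`alpha1 > 0.02`: breathing concentrates in-band phase energy over the
solid angle of a torso, which an empty bed cannot imitate. The
counting rule is fixed; the two threshold values are calibration
constants, chosen once on synthetic scenes (empty-bed windows give
zero qualifying cells, breathing scenes give dozens) and exposed in
`detector_config()`.

**Movement.** For every cell whose mean amplitude is within 30 dB of
the window's peak, the per-step changes of the unwrapped phase are
thresholded at 1.5 rad (at 20 Hz this corresponds to a radial speed of
about 11 mm/s, far above breathing speeds); the per-step count of
qualifying cells is smoothed with a causal 0.5 s moving average, and a
5 s interval is labelled "with movement" when the smoothed count
exceeds 5 anywhere inside it. Three implementation choices matter and
were fixed by experiment:

* the 30 dB amplitude gate is referenced to the window's *peak* mean
  amplitude. The natural alternative (30 dB above a noise-floor
  estimate) turned out to be unstable: at simulation scale the floor is
  sidelobe-limited and tracks overall scene brightness, so the gate
  content changed with the scene instead of with cell quality. The
  peak-referenced gate is invariant to global amplitude scaling, like
  the presence detector.
* the moving average is causal (trailing) with a zero-padded warm-up,
  so movement energy is never attributed to samples before the step
  that produced it and cannot leak backward across an interval
  boundary; complementarily, the first 0.5 s of each interval is not
  used for its classification, because the causal average there still
  summarizes steps from the previous interval. Ground-truth labels use
  the matching convention: an interval counts as "with movement" when
  an event overlaps it by more than 0.25 s - the raised-cosine tails
  of an event carry sub-millimetre, near-zero-velocity motion that no
  phase-step detector can or should register.
* fast motion aliases: a limb moving at tens of cm/s wraps the
  per-step phase uniformly into `(-pi, pi]`, so during a movement each
  affected cell exceeds the 1.5 rad threshold on roughly half the
  steps. The indicator is therefore a plateau at about half the number
  of affected cells, which is why the count threshold (5 cells) is
  meaningful even for strongly aliased motion.

## Pose and joints: the forked network

The two heatmap stacks (five indicator channels in azimuth-elevation
and in elevation-distance arrangement, each channel standardized to
zero mean and unit variance) feed two independent convolutional forks:
three 3x3 valid convolutions, one 2x2 max-pooling layer and dropout;
the flattened forks are concatenated into a four-layer MLP with two
dropout layers and a final head - either a 3-way softmax for
supine/prone/lateral classification (categorical cross-entropy) or 18
linear outputs for six torso joints (xiphoid, navel, shoulders, hips).

The regression loss is the mean absolute angle between the lines
connecting the radar to the true and predicted joint positions.
Internally each joint is predicted as `(a, b, r_norm)`: the raw pair
`(a, b)` is squashed smoothly into the direction-cosine disc via
`(u, v) = sqrt(0.995) (a, b) / sqrt(1 + a^2 + b^2)` (a hard clip would
have non-differentiable corners exactly where an untrained network
starts), the predicted direction is the unit vector
`(u, sqrt(1 - u^2 - v^2), v)`, and the angle gradient is computed in
the numerically stable form whose magnitude stays bounded as the angle
approaches zero. The angular loss cannot constrain the radial
coordinate at all, so training adds an L1 term on the z-scored distance
(weight 10 degrees per unit); without some radial term the distance
output would be untrained. Distances are z-scored with constants from
the training split, stored with the model. Activations are leaky ReLU
(slope 0.01): with plain ReLU a fraction of training runs lost enough
units early to stall permanently at the predict-the-mean plateau.
Optimization is minibatch Adam with early stopping on a person-disjoint
validation split; windows from one person never appear in more than one
of the train/validation/test splits, and `make_person_split()` enforces
this. Training is deterministic given the seed. Layer widths and filter
counts are pure configuration (defaults: 8/12/16 filters, 96/64/32/16
MLP), with no claim of matching any particular trained system.

## Respiration: traces, rate, phase shift

Movement-free windows are merged along time per cell by matching a
constant phase offset over the 5 s overlap (the mean difference),
which also absorbs changes of the selected range bin between windows.
The estimated joints split the torso footprint (the angular bounding
region of shoulders and hips, padded by one cell) at the perpendicular
bisector of the xiphoid-navel segment, chest on the shoulder side. One
refinement proved necessary: cells closer to the bisector than about
half a beamwidth are assigned to *neither* region. The imaging
point-spread function mixes chest and abdomen motion in the straddling
cells, and because the torso centre is also the brightest area, the
amplitude-weighted average would otherwise let the stronger region
dominate both traces (measured 48% amplitude leakage without the guard
band, 14% with it).

Per region, the unwrapped per-cell phase is band-passed to
0.05-6 Hz with a zero-phase forward-backward 4th-order Butterworth
filter (the band keeps the breathing fundamental and its first
harmonics while removing the static offset) and averaged with the mean
cell amplitude as weight. The breathing rate is estimated on the
abdomen trace by an STFT with 40 s segments and 5 s hop: each
demeaned, Hanning-tapered segment is scored per candidate fundamental
by the `1/h`-weighted sum of the power at the candidate and its first
two harmonics, and the maximizing candidate wins - summing harmonics
prevents the octave-down error a plain spectral argmax makes when the
waveform has strong harmonics. A subharmonic-preference step follows:
if half or a third of the winning candidate scores within 70% of it,
that lower candidate is taken instead. This guards against the
converse octave-up error: cells whose return fades through zero during
a breath pick up systematic near-2-pi phase slips at fixed breathing
phases, which put a coherent harmonic comb into the averaged trace,
and on a comb every multiple of the fundamental scores highly. A clean
fundamental is immune (its subharmonic scores about half). Segment
FFTs are zero-padded eightfold so the candidate grid (about 0.2
cycles/min) is much finer than the error budget; segments whose best
score is less than 3 dB above the median score (or negligible against
the total segment power) are flagged low-quality and return no rate. The chest-abdomen phase shift is
`Theta(t) = acos( <ra, rc> / (|ra| |rc|) )` over a 15 s window centred
at `t`; for same-frequency sinusoids this is their phase difference,
and values near 180 degrees flag paradoxical breathing. Note that with
10 s antiphase episodes inside a 15 s window the angle is biased low by
the window overhang; comparisons against scripted ground truth
therefore apply the same windowed estimator to the scripted
displacement series (the synthetic analogue of reference belts).

## The synthetic scene model: what it does and does not emulate

The generator stands in for a measurement campaign, so its defaults
are the study conditions, chosen once:

* **Body.** The torso is an elliptic cylinder (at least 200 surface
  scatterers on the radar-facing half, log-normal reflectivity, plus a
  sparsely sampled hidden half that the aspect weighting zeroes out but
  that keeps the geometry a full body), with head, limb and
  peripheral-clutter scatterers. Limbs are cylindrical surface patches
  with skin reflectivity whose specular line faces the radar; they
  breathe with the trunk section they rest against (chest- or
  abdomen-following by longitudinal position, at 0.3 of the trunk
  amplitude for arms and 0.1 for legs) - a rigidly static bright limb
  beside the chest would inject an arbitrary-phase component into the
  region-averaged respiratory trace that real bodies do not produce. Joints sit at fixed
  anthropometric fractions of height: xiphoid at 72% and navel at 60%
  from the feet, shoulders at 82% and hips at 48%, offset laterally by
  half the body width. The scene is built in a bed-fixed frame and
  rigidly transformed to the radar, which sits 0.8 m beside and 0.9 m
  above the mattress, boresight on the bed centre.
* **Poses.** Supine exposes the chest front (full breathing
  amplitude); prone exposes the flatter back (larger half-depth,
  narrower angular fan) with breathing attenuated and concentrated
  toward the lower back; lateral rolls the body 90 degrees so the
  width is vertical and the anterior surface faces the radar. These
  are structural differences, deliberately not just amplitude scalings
  (the per-channel standardization of the network inputs would erase a
  pure amplitude difference).
* **Breathing.** Sinusoid with optional second harmonic, normalized so
  the peak displacement equals the scripted amplitude; chest leads or
  lags the abdomen by a scripted offset, plus 180 degrees during
  asynchrony episodes (smooth 1.5 s transitions). The displacement
  direction is a 0.75/0.25 blend of the body's anterior axis and the
  local surface normal: a real torso wall moves as a coherent unit,
  and purely normal-directed motion of discrete scatterers produces
  several radians of differential two-way phase inside one resolution
  cell per breath - speckle fades and phase slips that real skin does
  not exhibit and that drowned the movement detector's rest baseline.
  Single-scatterer scenes (`point_scene`) keep pure normal motion for
  closed-form checks.
* **Movements.** Raised-cosine out-and-back excursions; limb
  movements are modelled as lifting a limb off the mattress (direction
  scattered about world-up), whole-body shifts as mostly horizontal
  rolls; breathing during the movement protocol uses quiet-breathing
  amplitudes (2.5/3.5 mm chest/abdomen).
* **Specularity.** Reflection off skin is strongly directional while
  the signal model assumes isotropic elements, so each scatterer's
  reflectivity is weighted by `cos^4` of the angle between its surface
  normal and the line of sight (exponent configurable; 0 disables).
  Blankets are not modelled beyond an optional uniform attenuation.

Not emulated: electromagnetic scattering beyond the cosine-power
surrogate, multipath, occlusion of far-side limbs by the body,
cloth/blanket physics, heartbeat micro-motion, and real anatomical
variability beyond height/width scaling. Passing the synthetic studies
therefore demonstrates that the *algorithms* recover what the scene
model encodes at realistic geometry, resolution and SNR - not that the
trained pose models would transfer to human data.

## Study configurations and problem sizes

All simulation studies are deterministic given a seed and sized for a
single CPU core:

* **Rate recovery** (`study_rate_recovery`): six supine scenes of
  120 s, scripted rates 7-24 cycles/min, 16 tones and an 8 x 8
  subarray (rate estimation needs no region separation), noiseless and
  at 15 dB raw SNR.
* **Phase shift** (`study_phase_shift`): eight persons, 100 s supine
  scenes with a 10 s antiphase episode, full 20 x 20 array with 16
  tones at 16 Hz frames. Separating chest from abdomen genuinely
  requires the full angular aperture - an 8-element subarray's beam is
  wider than the chest-abdomen separation, which was verified
  numerically, not assumed.
* **Movement** (`study_movement`): one protocol run of 41 limb
  movements (5-30 cm, 1-5 s) plus 4 whole-body shifts with 8-16 s
  rest gaps (about 12 minutes simulated), full array with 32 tones:
  resting limbs must be range-separated from the torso or their static
  returns mix into breathing cells.
* **Pose network** (`study_pose_net` on `generate_pose_dataset`): 312
  windows (8 synthetic persons x 3 poses x 13 placements), 16 s
  windows at 8 Hz, full array with a 17 x 21 azimuth-elevation crop;
  training runs 60 epochs (classification) and up to 250 epochs
  (regression) with early stopping. The mean-of-training-set predictor
  is the comparison baseline for joint regression.

The documented desk-scale tone counts trade range resolution (28-57 cm
instead of 5.75 cm) for speed where range structure is not the
quantity under test; every study that depends on a capability keeps
the hardware dimension that provides it.

## Numerical choices and degenerate inputs

Argmax ties resolve to the smaller index. The unwrapped-phase merge
requires at least one overlap sample. `add_noise` refuses an all-zero
cube (undefined signal power). `compute_indicators` rejects windows
where no cell passes the amplitude floor. `phase_shift_angle` rejects
zero-norm windows; `breathing_rate` flags flat spectra instead of
guessing. Grids require odd angular crop counts (the symmetric crop is
what makes the FFT-path axis reversal exact). All container writes are
bit-exact round trips.

## Known limitations

Absolute radiometric calibration is undefined; every threshold in dB
is relative to the window's own statistics. The phase-shift angle is
biased toward 0/180 degrees when the analysis window straddles an
episode boundary, an estimator property, not a bug. The movement
detector inherits a boundary effect: an event ending within half a
smoothing window of a 5 s boundary can label the neighbouring interval.
The pose models are tied to the simulated radar placement, and the
synthetic pose accuracy says nothing about MediaPipe-grade human
ground truth.
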