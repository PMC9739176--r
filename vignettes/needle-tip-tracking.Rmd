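---
title: "Needle-tip tracking from fibre-optic hydrophone frames: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Needle-tip tracking from fibre-optic hydrophone frames: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fohtrack)
```

## The problem

During ultrasound-guided needle procedures — regional anaesthesia, biopsy,
fetal interventions such as chorionic villus sampling — the needle tip must
be placed precisely, but its echo is often obscured by specular reflection
off the shaft, reverberation artefacts, or tissue heterogeneity. One remedy
is to make the needle an *active* receiver: a fibre-optic hydrophone (FOH),
a Fabry–Pérot pressure sensor on the tip of an optical fibre threaded
through the needle stylet, records the imaging probe's own transmissions.
Because each B-mode frame of a curvilinear (convex) probe is built from a
fan of scan lines transmitted in sequence, the set of waveforms the tip
receives during one frame encodes where the tip sits in that fan: *which*
scan lines insonify it strongly gives the angle, and *when* the pulse
arrives gives the range. `fohtrack` implements that pipeline end to end —
stream segmentation, matched filtering, polar localisation with
uncertainty, scan conversion with covariance propagation — together with a
synthetic curvilinear-field simulator and the evaluation harness used to
characterise accuracy, repeatability and SNR behaviour.

## Coordinate conventions

All positions live in the plane of the probe fan, with the origin at the
probe's centre of curvature. Polar coordinates are $(r, \theta)$: $r$ the
distance from the centre of curvature (mm), $\theta$ the angle from the
vertical (axial) axis, signed so that positive $\theta$ lies on the
positive lateral side. Cartesian coordinates use $x = r\sin\theta$
(lateral) and $y = r\cos\theta$ (axial, positive *into* the medium). With
this choice depth, range and image row index all increase together; the
screen-axis formulation that flips the vertical sign is treated purely as
a display convention. The probe face is the arc $r = \rho$ (radius of
curvature $\rho$), and a pulse received a time $t$ after transmission sits
at $r = ct + \rho$ for the system's assumed sound speed $c$.

Scan lines are evenly spaced in angle across the field of view, inclusive
of both edges: for a 55° fan with $N = 128$ lines the spacing is
$55/127 \approx 0.433$°. The true line layout of a commercial probe is
proprietary; every geometric parameter is configurable on
`probe_geometry()`.

## The tracking algorithm

Each frame is an $n_\text{samples} \times N$ matrix of voltages, one
column per scan line, with column time zero at the line trigger.

**Preprocessing.** Every column is cross-correlated with a template pulse
(`matched_filter()`), computed in the frequency domain with zero padding
and aligned so a column equal to the template starting at sample $k$ peaks
at sample $k$. The envelope is then taken as the magnitude of the analytic
signal (`envelope()`), which is ripple-free for band-limited pulses. The
default template is the simulator's zero-angle pulse; users with real
recordings can supply a measured template (`read_template()`).

**SNR gate.** The frame SNR is the peak absolute value over the common
noise RMS, in dB; the noise level is the mean per-waveform RMS of
noise-only frames processed through the same stages. Frames below the gate
(default 12 dB) yield no position. The gate default is a documented
choice: enveloped matched-filtered noise has a peak-to-RMS ratio around
10–12 dB for full-size frames, so 12 dB rejects noise-only frames while
passing genuine low-SNR tissue frames (≈30 dB) by a wide margin. Because
the noise statistic grows slowly (logarithmically) with frame size, the
rejection margin is thinner for very large frames — a limitation worth
knowing when changing window length or line count.

**Angle.** Column energies $e_n$ (sum of squared processed samples) are
thresholded at −6 dB relative to the strongest column, which stops noisy
lines biasing the estimate. If the energy distribution has sufficient
dynamic range (max ≥ 6 dB above the median column energy — the criterion
is our own, the requirement for *some* dynamic-range condition is
inherited), the angle is the energy centre of mass
$\bar\theta = \sum_n \theta_n e_n / \sum_n e_n$; otherwise the tracker
falls back to the maximum-amplitude pixel. The angular uncertainty is the
weighted RMS deviation of the thresholded distribution with an
$N'/(N'-1)$ small-sample correction, $N'$ being the number of columns
with nonzero energy. The source formula for this spread is typeset
ambiguously; the literal alternative reading (dividing the weighted sum
of squares by $N'(N'-1)\sum e_n$) is available via
`weighted_angle_spread(..., form = "printed")` for comparison, and no
claim is made about which the original system used.

**Range.** On the maximum-energy surviving column, the cumulative
integral of the squared envelope is evaluated inside a gate of ±8
template lengths around the global peak (the gate stops the noise floor
inflating the integral). With $t_{0.1}$ and $t_{0.9}$ the times at which
it reaches 10% and 90% of its final value (located by linear
interpolation, treating sample $i$ as covering $[(i-1)/f_s, i/f_s)$ — a
convention that makes the rule exact for rectangular envelopes), the
pulse duration is $1.25\,\delta t$ with $\delta t = t_{0.9} - t_{0.1}$,
the pulse start is $t_{0.1} - 0.125\,\delta t$, and
$r = c(t_\text{start} - t_\text{delay}) + \rho$ with
$\sigma_r = 1.25\,c\,\delta t$.

One subtlety is ours to own: after matched filtering, the processed pulse
is the (symmetric) correlation of pulse with template, so the onset rule
reads the start of that symmetric envelope, which *leads* the true pulse
start by a fixed template-dependent amount. `localise_frame()` measures
this offset once per template by running the template itself through the
identical pipeline and subtracts it, keeping range estimates unbiased
without per-frame tuning.

**Scan conversion and uncertainty.** The polar estimate maps to Cartesian
by the exact trigonometric formulas. Uncertainty is propagated to first
order: a diagonal covariance $\mathrm{diag}(\sigma_r^2, (r\tan
\sigma_\theta)^2)$ in the radial/tangential frame is rotated by
$90° - \theta$ into image axes, so on-axis the radial uncertainty is
purely axial. First-order propagation is accurate in the tracker's
operating regime ($\sigma_r$ 1–3 mm set by the pulse length,
$\sigma_\theta$ a fraction of a degree to about 2°); for much larger
angular spreads near the vertical axis the neglected second-order
curvature term ($\approx r\sigma_\theta^2/\sqrt2$ on the axial sd)
becomes visible, which is an inherent limit of the linearised method,
not of its implementation.

## The simulator

The synthetic-data generator exists so the tracker can be exercised
against known ground truth. It models the field a *point receiver* sees:

- **Pulse**: Gaussian-windowed cosine at 2 MHz with 60% fractional
  bandwidth, sampled at 10 MHz. When the needle is angled, a second
  Gaussian-windowed cosine at 0.5 MHz is added with amplitude ramping
  linearly from 0 at 0° to 0.67 at 40° (flat beyond). This calibrates the
  model to the observed behaviour of the physical sensor, whose raw
  amplitude rises ~67% between 0° and 40° through a low-frequency
  component that the matched filter later removes — which is exactly why
  the processed response is flat with angle (within ±10% in our
  regression tests). The ramp shape is a modelling choice, not a measured
  directivity.
- **Beam profiles**: Gaussian lateral (in scan angle, σ in degrees) and
  elevational (in mm) sensitivity profiles with piecewise-linear
  "hourglass" widths, minimal at the transmit focal depth (defaults: σ
  0.7° + 0.008°/mm of defocus laterally; 4 mm + 0.08 mm/mm
  elevationally), plus a beam-spreading amplitude loss proportional to
  the lateral width ratio. These surrogates reproduce the qualitative
  focal-depth contrast of a real system (tight bright beam near focus,
  broad weak beam far from it); a full diffraction simulation is
  deliberately out of scope, so absolute beam widths should not be read
  as properties of any physical probe.
- **Arrival**: the pulse is inserted at the sample nearest
  $t_\text{delay} + (r-\rho)/c$ (trigger-to-transmit delay default
  20 µs), scaled per line by the beam profiles and, for tissue-like
  scenes, by attenuation in dB/(cm·MHz) over the path $r - \rho$ (0 for
  water scenes, ≈1 for tissue-like ones).
- **Noise**: white Gaussian, i.i.d. per sample. SNR is defined as clean
  peak over noise RMS. Within a dataset one *common* noise level is used
  for all frames — referenced to the brightest in-plane scene — matching
  the common-noise-level methodology of the physical experiments and
  making SNR fall off as the tip moves out of plane or out of focus.
- **Determinism**: each frame's noise is drawn under a seed derived from
  the dataset master seed, so identical (scene, seed) pairs give
  bit-identical frames.

What the simulator does *not* model: needle-shaft echoes, reverberation,
side lobes, sound-speed heterogeneity and phase aberration. Passing the
simulated accuracy bounds therefore demonstrates that the *algorithm*
adds little error on top of the field model; it does not predict
performance in tissue, where those omitted effects dominated the physical
system's error budget.

## The experiments reproduced in simulation

- **In-plane grid** (`generate_grid_dataset()`): true positions on a 5 mm
  Cartesian lattice on the right-hand half of the imaging plane between
  40 and 140 mm below the probe face, restricted to the fan — 356
  positions with the default geometry ($\rho$ = 68 mm; this radius is our
  configurable default, chosen as plausible for an abdominal convex probe
  and consistent with that lattice count, not a manufacturer figure) —
  with 18 frames per position at 60 dB SNR (the in-water regime). Error
  is the mean displacement vector of the tracked positions over the
  frames at a position (Cartesian and polar); repeatability is their
  per-axis sample standard deviation. Spatial means of the magnitudes
  summarise the whole area.
- **Elevational sweep** (`generate_elevation_sweep()`): tip fixed
  in-plane at 145 mm depth, stepped −36…36 mm out of plane in 1 mm steps
  (73 positions), at two focal depths (15 and 140 mm), yielding the
  displacement/repeatability/SNR-vs-z curves of `elevation_analysis()`.
- **Angle sweep** (`generate_angle_sweep()`): tip on-axis at 150 mm,
  thirteen needle angles 0–60°; `angle_analysis()` reports raw and
  processed amplitudes.
- **Label correction** (`label_offset_correction()`): manually labelled
  image positions are displaced along the needle shaft from the sensor
  position; the correction subtracts a shaft-directed offset (e.g.
  3.5 mm at the insertion angle).
- **Uncertainty validity** (`uncertainty_correlation()`): Pearson
  correlation between estimated uncertainty magnitudes and measured
  repeatability magnitudes.

Problem sizes in the test-suite and acceptance runs are desk scale by
design: the grid experiment is run on every 2nd position with 6 frames
per position (178 positions, 1068 frames), which our tests show already
estimates the spatial means stably; the full 356 × 18 run is a
straightforward (if slower) call with the same defaults.

## Numerical choices and degenerate inputs

- Matched filtering pads columns to a power-of-two length; acquisition
  windows are rounded up to 2-3-5-smooth lengths so per-column FFTs never
  hit a large prime.
- Cumulative-energy crossings are linearly interpolated; ties in argmax
  (equal energy or amplitude) resolve to the lowest column, then lowest
  sample index.
- All-zero frames, gated-out frames and out-of-fan estimates return
  `valid = FALSE` rather than raising; data-content errors never abort a
  tracking run.
- A single energetic column forces $N' = 1$ and an angular spread of 0.
- The Kalman option (`kalman_smooth()`) is a standard linear filter
  (constant-velocity or constant-acceleration), with measurement
  covariance per frame from the propagated $2\times2$ covariance and
  invalid frames handled as missing measurements. The default process
  noise (2 mm²/s³ at 18 Hz) gives roughly a threefold RMS jitter
  reduction on a stationary high-SNR track; it trades jitter for lag and
  is configurable.

## Worked example

```{r example, eval = FALSE}
geom <- probe_geometry()          # 68 mm radius, 55 deg, 128 lines, 300 mm
pulse <- pulse_model()            # 2 MHz, 60% bandwidth
sim <- generate_grid_dataset(geom, pulse, n_frames_per_pos = 6,
                             snr_db = 60, seed = 1)
sim$scenes <- sim$scenes[sim$scenes$position_id %% 2 == 1, ]

estimates <- track_frames(sim)
metrics <- position_metrics(estimates, sim$truth)
spatial_summary(metrics)
plot_metric_field(metrics, "e_mag_mm")
```

## Known limitations

- Single point scatterer only; no shaft echo or multi-target ambiguity,
  so the max-pixel fallback path is exercised far less than it would be
  on real near-field data.
- Beam-width surrogates are qualitative; out-of-plane curves should be
  compared in shape, not absolute extent.
- First-order covariance propagation under-reports the axial spread for
  angular uncertainties beyond a few degrees near the vertical axis (see
  above).
- The SNR gate margin narrows logarithmically with frame size.
- Isotropic pixels are assumed in image calibration; anisotropic
  calibration is out of scope.
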