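# fohtrack

Needle-tip tracking from fibre-optic hydrophone (FOH) ultrasound frames.

During ultrasound-guided needle procedures the tip is easily lost: specular
reflection off the shaft, reverberation and tissue heterogeneity can all hide
it in the B-mode image, and misplacement risks nerve damage, organ injury or,
in fetal medicine, pregnancy loss. An alternative to making the needle *look*
brighter is to make it *listen*: a fibre-optic hydrophone — a Fabry–Pérot
pressure sensor on a 150 µm fibre threaded through the needle stylet —
receives the imaging probe's own transmissions at the tip. Because a
curvilinear probe sweeps its scan lines through a fan, one B-mode frame's
worth of received waveforms pins the tip down in the fan's polar
coordinates, and the position can be drawn back onto the clinical image as a
cross-hair.

`fohtrack` is an R implementation of that pipeline for engineers and
researchers working on in-needle receiver tracking:

- **Framing** — split a digitizer voltage stream into per-frame waveform
  arrays ("FOH frames", time samples × scan lines) using line-trigger and
  frame-gate signals.
- **Preprocessing** — matched filtering against a pulse template and
  analytic-signal envelope detection; common-noise-level estimation and SNR
  gating.
- **Localisation** — tip angle from the energy centre of mass across scan
  lines after a −6 dB column threshold,

  θ̄ = Σₙ θₙeₙ / Σₙ eₙ,  σθ = √(Σₙ eₙ(θₙ − θ̄)² / Σₙ eₙ) · √(N′/(N′−1)),

  and range from the pulse time of arrival via the 10–90% cumulative-energy
  onset rule (pulse start t₀.₁ − 0.125 δt, duration 1.25 δt), mapped through
  r = c·t + ρ with σᵣ = 1.25·c·δt.
- **Scan conversion** — (r, θ) → (x, y) = (r sin θ, r cos θ) with first-order
  covariance propagation: K = R·diag(σᵣ², (r tan σθ)²)·Rᵀ; plus one-shot
  pixel calibration of a B-mode image (fan apex + pixel size) and cross-hair
  overlay rendering.
- **Simulator** — synthetic curvilinear-field frames for a point receiver at
  known pose (Gaussian beam profiles, angle-dependent low-frequency pulse
  component, configurable SNR/attenuation/focal depth), reproducing the
  layouts of the in-plane accuracy grid (356 positions), the elevational
  sweep (73 positions) and the needle-angle sweep (13 angles).
- **Evaluation** — tracking error (mean displacement vector), repeatability
  (per-axis sd), repeat averaging, spatial summaries, out-of-plane and angle
  analyses, label-offset correction, uncertainty–repeatability correlation,
  and optional constant-velocity / constant-acceleration Kalman smoothing.

Everything is tibble-first: `track_frames()` returns one row per frame,
`position_metrics()` one row per location, and results chain with the pipe
into `spatial_summary()` or the plotting helpers
(`plot_metric_field()`, `plot_elevation_curves()`, `plot_angle_amplitude()`,
`autoplot()` on a frame).

## Worked example

Simulate a reduced in-plane accuracy grid (every 8th position, 3 frames per
position, 60 dB SNR), run the tracker, and summarise:

```r
library(fohtrack)

geom  <- probe_geometry()   # rho 68 mm, 55 deg fan, 128 lines, 300 mm depth
pulse <- pulse_model()      # 2 MHz centre frequency, 60% bandwidth
sim   <- generate_grid_dataset(geom, pulse, n_frames_per_pos = 6,
                               snr_db = 60, seed = 1)
sim$scenes <- sim$scenes[sim$scenes$position_id %% 8 == 1 &
                         sim$scenes$frame <= 3, ]

estimates <- track_frames(sim)
estimates |> dplyr::select(position_id, frame, r_mm, theta_deg,
                           x_mm, y_mm, sigma_x_mm, sigma_y_mm, snr_db)
#> # A tibble: 135 × 9
#>   position_id frame  r_mm theta_deg      x_mm  y_mm sigma_x_mm sigma_y_mm snr_db
#> 1           1     1  108.  0.000300  0.000566  108.      0.953       1.55   61.5
#> 2           1     2  108. -0.000176 -0.000333  108.      0.954       1.56   61.5
#> 3           1     3  108. -0.000311 -0.000587  108.      0.953       1.56   61.5
#> # ...

metrics <- position_metrics(estimates, sim$truth)
spatial_summary(metrics)
#> # A tibble: 2 × 5
#>   metric        mean     sd     p95     n
#> 1 e_mag_mm   0.0927  0.0620 0.182      45
#> 2 rep_mag_mm 0.00851 0.0302 0.00613    45
```

Each estimate row is a tracked tip position: `r_mm`/`theta_deg` in the fan's
polar frame with uncertainties `sigma_r_mm`/`sigma_theta_deg`, and the
scan-converted `x_mm`/`y_mm` with the propagated per-axis uncertainties
(here ~0.95 mm tangentially, dominated by beam width, and ~1.55 mm radially,
the pulse length). The summary says that at 60 dB SNR the tracker's mean
error magnitude over the scanned area is ≈0.09 mm with ≈0.009 mm
repeatability — the algorithmic floor on a clean synthetic field, well below
what hardware systematics add on a physical system.

A command-line front end wrapping the same functions is installed at
`exec/fohtrack` (`simulate`, `track`, `evaluate`, `playback`, each with
`--config`, `--seed`, `--out`).

## Scope

The simulator models a single point receiver in a Gaussian-beam fan — no
shaft echoes, reverberation, side lobes or sound-speed heterogeneity — so
results on synthetic data characterise the algorithm, not any physical
probe. See the methods vignette (`vignettes/needle-tip-tracking.Rmd`) for
the model, parameter defaults and known limitations.
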