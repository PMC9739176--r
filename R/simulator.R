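#' Ultrasound pulse model for the synthetic field
#'
#' The received pulse is modelled as a Gaussian-windowed sinusoid at the
#' probe's centre frequency, optionally mixed with a second Gaussian-windowed
#' sinusoid at a low frequency whose relative amplitude grows with the needle
#' insertion angle. The low-frequency component mimics the angle-dependent
#' energy observed below the imaging band when the needle is steeply angled;
#' because it lies outside the matched-filter band it is removed by
#' preprocessing, which is what equalises the tracker's directional response.
#'
#' @param f0 Centre frequency (Hz).
#' @param fractional_bandwidth Full -6 dB width of the amplitude spectrum
#'   divided by `f0` (unitless, in (0, 2)).
#' @param low_freq_fraction Function of needle angle (degrees) returning the
#'   amplitude of the low-frequency component relative to the main one. The
#'   default ramps linearly from 0 at 0 degrees to 0.67 at 40 degrees and is
#'   flat beyond, so the raw peak grows by ~67% between 0 and 40 degrees.
#' @param low_freq_f Frequency of the low-frequency component (Hz).
#' @return An object of class `pulse_model`.
#' @export
pulse_model <- function(f0 = 2e6,
                        fractional_bandwidth = 0.6,
                        low_freq_fraction = function(angle_deg) {
                          0.67 * pmin(pmax(angle_deg, 0), 40) / 40
                        },
                        low_freq_f = 0.5e6) {
  stopifnot(
    "f0 must be > 0" = f0 > 0,
    "fractional_bandwidth must be in (0, 2)" =
      fractional_bandwidth > 0 && fractional_bandwidth < 2,
    "low_freq_fraction must be a function" = is.function(low_freq_fraction),
    "low_freq_f must be in (0, f0)" = low_freq_f > 0 && low_freq_f < f0
  )
  structure(
    list(f0 = f0, fractional_bandwidth = fractional_bandwidth,
         low_freq_fraction = low_freq_fraction, low_freq_f = low_freq_f),
    class = "pulse_model"
  )
}

# Gaussian-envelope time constant (s) for a -6 dB fractional bandwidth b at
# carrier f: amplitude spectrum exp(-(f - f0)^2 / (2 sigma_f^2)) falls to 1/2
# at (b/2) f0, so sigma_f = b f0 / (2 sqrt(2 log 2)).
gaussian_sigma_t <- function(f0, fractional_bandwidth) {
  sigma_f <- fractional_bandwidth * f0 / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

#' Synthesise a received ultrasound pulse
#'
#' Builds the time-domain pulse waveform the simulator inserts into each
#' scan line: a Gaussian-windowed cosine at `f0` (unit peak) plus, when the
#' needle is angled, a Gaussian-windowed cosine at `low_freq_f` scaled by
#' `low_freq_fraction(needle_angle)`. The low-frequency window is stretched
#' by `f0 / low_freq_f` so both components hold the same number of cycles.
#' The waveform is forced to zero mean and has odd length with its peak at
#' the centre sample.
#'
#' @param model A [pulse_model()].
#' @param sample_rate Sampling rate (Hz); `f0` must be below Nyquist.
#' @param needle_angle Needle insertion angle (degrees).
#' @return Numeric waveform vector with attribute `centre` (index of the
#'   peak sample).
#' @export
synthesize_pulse <- function(model, sample_rate, needle_angle = 0) {
  stopifnot(inherits(model, "pulse_model"))
  if (model$f0 >= sample_rate / 2) {
    stop("aliasing: f0 must be below the Nyquist frequency", call. = FALSE)
  }
  sigma_t <- gaussian_sigma_t(model$f0, model$fractional_bandwidth)
  sigma_low <- sigma_t * model$f0 / model$low_freq_f
  half <- ceiling(4 * max(sigma_t, sigma_low) * sample_rate)
  t <- (-half:half) / sample_rate
  w <- cos(2 * pi * model$f0 * t) * exp(-t^2 / (2 * sigma_t^2))
  frac <- model$low_freq_fraction(needle_angle)
  if (frac > 0) {
    w <- w + frac * cos(2 * pi * model$low_freq_f * t) *
      exp(-t^2 / (2 * sigma_low^2))
  }
  w <- w - mean(w)
  structure(w, centre = half + 1L)
}

#' Simulated beam widths of the curvilinear field
#'
#' Piecewise-linear "hourglass" beam profiles, minimal at the transmit focal
#' depth and widening linearly with distance from it. `lateral_beamwidth()`
#' returns the Gaussian sigma of the scan-line-direction sensitivity profile
#' in degrees of fan angle; `elevational_beamwidth()` the Gaussian sigma of
#' the out-of-plane (slice-thickness) profile in mm. A full diffraction
#' simulation is deliberately out of scope; these surrogates reproduce the
#' qualitative focal-depth contrast of the physical system (tighter, stronger
#' beam near focus; broad, weak beam far from it).
#'
#' @param depth_mm Depth below the probe face (mm).
#' @param focal_depth_mm Transmit focal depth (mm).
#' @param width_at_focus Sigma at the focal depth (deg or mm).
#' @param spread Widening rate per mm of defocus (deg/mm or mm/mm).
#' @return Numeric sigma, same shape as `depth_mm`.
#' @export
lateral_beamwidth <- function(depth_mm, focal_depth_mm,
                              width_at_focus = 0.7, spread = 0.008) {
  width_at_focus + spread * abs(depth_mm - focal_depth_mm)
}

#' @rdname lateral_beamwidth
#' @export
elevational_beamwidth <- function(depth_mm, focal_depth_mm,
                                  width_at_focus = 4, spread = 0.08) {
  width_at_focus + spread * abs(depth_mm - focal_depth_mm)
}

#' Ground-truth scene for frame synthesis
#'
#' Describes one true needle-tip pose and the acoustic conditions under
#' which a synthetic FOH frame is generated.
#'
#' @param x_mm,y_mm In-plane tip position (mm, Cartesian relative to the
#'   centre of curvature; `y` positive into the medium).
#' @param z_mm Elevational (out-of-plane) tip offset (mm).
#' @param needle_angle_deg Needle insertion angle relative to horizontal
#'   (degrees); affects the pulse's low-frequency content only.
#' @param snr_db Peak-signal-to-RMS-noise ratio (dB); `Inf` for noise-free.
#' @param focal_depth_mm Transmit focal depth (mm).
#' @param attenuation_db_cm_mhz Acoustic attenuation (dB/(cm MHz)); 0 for
#'   water scenes, ~1 for tissue-like scenes.
#' @param trigger_to_transmit_delay_s Delay between line trigger and actual
#'   transmission (seconds).
#' @param lateral_bw,elevational_bw Optional replacement beam-width
#'   functions `(depth_mm, focal_depth_mm) -> sigma`.
#' @return An object of class `simulation_scene`.
#' @export
simulation_scene <- function(x_mm, y_mm, z_mm = 0, needle_angle_deg = 0,
                             snr_db = Inf, focal_depth_mm = 15,
                             attenuation_db_cm_mhz = 0,
                             trigger_to_transmit_delay_s = 2e-5,
                             lateral_bw = lateral_beamwidth,
                             elevational_bw = elevational_beamwidth) {
  stopifnot(
    "snr_db must be finite or +Inf" = !is.na(snr_db) && snr_db > -Inf,
    "focal_depth_mm must be > 0" = focal_depth_mm > 0
  )
  structure(
    list(x_mm = x_mm, y_mm = y_mm, z_mm = z_mm,
         needle_angle_deg = needle_angle_deg, snr_db = snr_db,
         focal_depth_mm = focal_depth_mm,
         attenuation_db_cm_mhz = attenuation_db_cm_mhz,
         trigger_to_transmit_delay_s = trigger_to_transmit_delay_s,
         lateral_bw = lateral_bw, elevational_bw = elevational_bw),
    class = "simulation_scene"
  )
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-scan-line clean amplitudes for a scene: Gaussian lateral and
# elevational beam profiles times frequency-dependent attenuation over the
# acoustic path r - rho.
scene_amplitudes <- function(scene, geometry, pulse) {
  pol <- cartesian_to_polar(scene$x_mm, scene$y_mm)
  depth <- pol$r - geometry$rho_mm
  angles <- scan_line_angles(geometry)
  w_lat <- scene$lateral_bw(depth, scene$focal_depth_mm)
  w_elev <- scene$elevational_bw(depth, scene$focal_depth_mm)
  # beam-spreading loss relative to a tip at the focal depth
  loss <- scene$lateral_bw(scene$focal_depth_mm, scene$focal_depth_mm) / w_lat
  atten <- 10^(-scene$attenuation_db_cm_mhz * (depth / 10) *
                 (pulse$f0 / 1e6) / 20)
  a <- exp(-(pol$theta_deg - angles)^2 / (2 * w_lat^2)) *
    exp(-scene$z_mm^2 / (2 * w_elev^2)) * loss * atten
  list(a = a, r = pol$r, theta = pol$theta_deg, depth = depth)
}

# Clean (noise-free) frame matrix for a scene.
sim_clean_frame <- function(scene, geometry, pulse, sample_rate, window) {
  amp <- scene_amplitudes(scene, geometry, pulse)
  if (abs(amp$theta) > geometry$fov_deg / 2 + 5 ||
      amp$depth <= 0 || amp$depth > geometry$imaging_depth_mm) {
    stop("tip outside the simulated fan", call. = FALSE)
  }
  wave <- synthesize_pulse(pulse, sample_rate, scene$needle_angle_deg)
  arrival <- scene$trigger_to_transmit_delay_s +
    (amp$depth / 1000) / geometry$sound_speed_mps
  s0 <- round(arrival * sample_rate) + 1L
  if (s0 < 1) stop("arrival before acquisition start", call. = FALSE)
  if (s0 + length(wave) - 1L > window) {
    stop("window too short for pulse arrival; increase window", call. = FALSE)
  }
  m <- matrix(0, nrow = window, ncol = geometry$n_lines)
  idx <- s0:(s0 + length(wave) - 1L)
  for (n in which(amp$a > 1e-8)) {
    m[idx, n] <- amp$a[n] * wave
  }
  m
}

#' Generate one synthetic FOH frame
#'
#' Simulates the frame a point hydrophone receiver at the scene's tip pose
#' would record: each scan line holds the model pulse scaled by the lateral
#' and elevational Gaussian beam profiles and attenuation, inserted at the
#' sample nearest `trigger_to_transmit_delay + (r - rho) / c`, plus white
#' Gaussian noise whose RMS makes the clean-frame peak to noise-RMS ratio
#' equal `snr_db` (unless a common `noise_rms` is imposed, as the dataset
#' generators do to share one noise level across positions).
#'
#' @param scene A [simulation_scene()].
#' @param geometry A [probe_geometry()].
#' @param pulse A [pulse_model()].
#' @param sample_rate Sampling rate (Hz).
#' @param window Samples per scan line; see [default_window()].
#' @param seed Integer seed for the noise draw (`NULL` to use the current
#'   RNG state). Identical scene and seed give bit-identical frames.
#' @param noise_rms Optional fixed noise RMS (volts) overriding the
#'   per-frame `snr_db` scaling.
#' @param frame_index Index stored on the frame.
#' @return A [foh_frame()].
#' @export
generate_frame <- function(scene, geometry, pulse, sample_rate = 10e6,
                           window = default_window(geometry, sample_rate, pulse),
                           seed = NULL, noise_rms = NULL, frame_index = 1L) {
  stopifnot(inherits(scene, "simulation_scene"),
            inherits(geometry, "probe_geometry"),
            inherits(pulse, "pulse_model"))
  clean <- sim_clean_frame(scene, geometry, pulse, sample_rate, window)
  if (is.null(noise_rms)) {
    noise_rms <- if (is.finite(scene$snr_db)) {
      max(abs(clean)) / 10^(scene$snr_db / 20)
    } else 0
  }
  if (noise_rms > 0) {
    noise <- with_seed(seed, matrix(
      stats::rnorm(length(clean), sd = noise_rms),
      nrow = nrow(clean)
    ))
    clean <- clean + noise
  }
  foh_frame(clean, sample_rate, scan_line_angles(geometry),
            frame_index = frame_index,
            trigger_to_transmit_delay = scene$trigger_to_transmit_delay_s)
}

#' Default acquisition window per scan line
#'
#' One-way travel time to the configured imaging depth, plus the trigger
#' delay and a pulse-length margin, converted to samples.
#'
#' @inheritParams generate_frame
#' @param delay_s Trigger-to-transmit delay (seconds).
#' @return Window length in samples.
#' @export
default_window <- function(geometry, sample_rate = 10e6, pulse = pulse_model(),
                           delay_s = 2e-5) {
  travel <- (geometry$imaging_depth_mm / 1000) / geometry$sound_speed_mps
  margin <- length(synthesize_pulse(pulse, sample_rate)) + 8L
  # round up to a 2-3-5-smooth length so per-column FFTs stay fast
  next_fast_len(ceiling((delay_s + travel) * sample_rate) + margin)
}

# Shared constructor for lazy simulated datasets: scenes are tabulated, and
# frames are synthesised on demand (a full grid run would not fit in memory).
new_foh_simulation <- function(scenes, truth, geometry, pulse, sample_rate,
                               window, snr_db, focal_depth_mm,
                               attenuation_db_cm_mhz, delay_s, seed, kind) {
  # noise reference: the brightest scene — in plane first, then nearest the
  # focal depth
  depth_gap <- abs(sqrt(truth$x_mm^2 + truth$y_mm^2) - geometry$rho_mm -
                     focal_depth_mm)
  ref_id <- truth$position_id[order(abs(truth$z_mm), depth_gap)][1]
  ref_row <- which(scenes$position_id == ref_id)[1]
  sim <- structure(
    list(scenes = scenes, truth = truth, geometry = geometry, pulse = pulse,
         sample_rate = sample_rate, window = window, snr_db = snr_db,
         focal_depth_mm = focal_depth_mm,
         attenuation_db_cm_mhz = attenuation_db_cm_mhz,
         delay_s = delay_s, seed = seed, kind = kind, noise_rms = 0),
    class = "foh_simulation"
  )
  if (is.finite(snr_db)) {
    # one common noise level for the whole dataset, referenced to the clean
    # peak of the scene nearest the focal depth
    ref_clean <- sim_clean_frame(sim_scene(sim, ref_row), geometry, pulse,
                                 sample_rate, window)
    sim$noise_rms <- max(abs(ref_clean)) / 10^(snr_db / 20)
  }
  sim
}

# Scene object for row i of a simulation's scene table.
sim_scene <- function(sim, i) {
  row <- sim$scenes[i, ]
  simulation_scene(
    x_mm = row$x_mm, y_mm = row$y_mm, z_mm = row$z_mm,
    needle_angle_deg = row$angle_deg, snr_db = sim$snr_db,
    focal_depth_mm = sim$focal_depth_mm,
    attenuation_db_cm_mhz = sim$attenuation_db_cm_mhz,
    trigger_to_transmit_delay_s = sim$delay_s
  )
}

#' Materialise one frame of a simulated dataset
#'
#' @param sim A `foh_simulation` from one of the dataset generators.
#' @param i Row index into `sim$scenes`.
#' @return A [foh_frame()].
#' @export
sim_frame <- function(sim, i) {
  stopifnot(inherits(sim, "foh_simulation"), i >= 1, i <= nrow(sim$scenes))
  generate_frame(
    sim_scene(sim, i), sim$geometry, sim$pulse, sim$sample_rate, sim$window,
    seed = sim$scenes$seed[i],
    noise_rms = if (is.finite(sim$snr_db)) sim$noise_rms else 0,
    frame_index = sim$scenes$frame[i]
  )
}

#' @export
print.foh_simulation <- function(x, ...) {
  cat(sprintf(
    "<foh_simulation: %s> %d positions x %d frames (%d total), SNR %g dB\n",
    x$kind, nrow(x$truth), max(x$scenes$frame), nrow(x$scenes), x$snr_db
  ))
  invisible(x)
}

# Expand a truth table into a per-frame scene table with derived seeds.
expand_scenes <- function(truth, n_frames, seed) {
  scenes <- tidyr::expand_grid(truth, frame = seq_len(n_frames))
  scenes$seed <- (seed + seq_len(nrow(scenes))) %% .Machine$integer.max
  scenes
}

#' Simulated in-plane accuracy grid experiment
#'
#' Generates the in-plane accuracy dataset: true tip positions on a Cartesian
#' lattice on the right-hand side of the imaging plane (`x >= 0`), between
#' `depth_range` mm below the probe face, restricted to the probe fan, with
#' repeated noisy frames per position. The default 5 mm lattice between 40
#' and 140 mm yields 356 positions with the default geometry.
#'
#' @inheritParams generate_frame
#' @param grid_spec List with `depth_range` (mm below the probe face),
#'   `spacing` (mm) and `side` (`"right"` or `"both"`).
#' @param n_frames_per_pos Frames per position.
#' @param snr_db Dataset SNR (dB); one common noise level is used for all
#'   frames, referenced to the clean peak nearest the focal depth.
#' @param seed Integer master seed; per-frame seeds are derived from it.
#' @param focal_depth_mm Transmit focal depth (mm).
#' @param attenuation_db_cm_mhz Attenuation (dB/(cm MHz)); 0 = water.
#' @param delay_s Trigger-to-transmit delay (seconds).
#' @return A `foh_simulation` whose `truth` tibble has one row per position
#'   (`position_id`, `x_mm`, `y_mm`, `z_mm`, `angle_deg`) and whose `scenes`
#'   tibble has one row per frame.
#' @export
generate_grid_dataset <- function(geometry = probe_geometry(),
                                  pulse = pulse_model(),
                                  grid_spec = list(depth_range = c(40, 140),
                                                   spacing = 5,
                                                   side = "right"),
                                  n_frames_per_pos = 18,
                                  snr_db = 60,
                                  seed = 1,
                                  sample_rate = 10e6,
                                  window = default_window(geometry, sample_rate,
                                                          pulse, delay_s),
                                  focal_depth_mm = 15,
                                  attenuation_db_cm_mhz = 0,
                                  delay_s = 2e-5) {
  sp <- grid_spec$spacing
  depths <- seq(grid_spec$depth_range[1], grid_spec$depth_range[2], by = sp)
  half_fan <- geometry$fov_deg / 2
  xmax <- max((geometry$rho_mm + depths) * tan(half_fan * pi / 180))
  xs <- seq(0, ceiling(xmax / sp) * sp, by = sp)
  if (identical(grid_spec$side, "both")) xs <- sort(unique(c(-xs, xs)))
  grid <- tidyr::expand_grid(depth = depths, x_mm = xs)
  grid$y_mm <- geometry$rho_mm + grid$depth
  pol <- cartesian_to_polar(grid$x_mm, grid$y_mm)
  inside <- abs(pol$theta_deg) <= half_fan
  if (any(!inside)) {
    grid <- grid[inside, ]
  }
  truth <- tibble::tibble(
    position_id = seq_len(nrow(grid)),
    x_mm = grid$x_mm, y_mm = grid$y_mm, z_mm = 0, angle_deg = 0
  )
  new_foh_simulation(
    expand_scenes(truth, n_frames_per_pos, seed), truth, geometry, pulse,
    sample_rate, window, snr_db, focal_depth_mm, attenuation_db_cm_mhz,
    delay_s, seed, kind = "grid"
  )
}

#' Simulated out-of-plane (elevational) sweep experiment
#'
#' The tip is held at a fixed in-plane position on the central axis at
#' `depth_mm` below the probe face and stepped through elevational offsets
#' `z`; the default -36 to 36 mm in 1 mm steps gives 73 positions.
#'
#' @inheritParams generate_grid_dataset
#' @param depth_mm Tip depth below the probe face (mm).
#' @param z_range Elevational range (mm).
#' @param step Elevational step (mm).
#' @param n_frames Frames per position.
#' @return A `foh_simulation` (kind `"elevation"`).
#' @export
generate_elevation_sweep <- function(geometry = probe_geometry(),
                                     pulse = pulse_model(),
                                     depth_mm = 145,
                                     z_range = c(-36, 36),
                                     step = 1,
                                     focal_depth_mm = 140,
                                     n_frames = 18,
                                     snr_db = 60,
                                     seed = 1,
                                     sample_rate = 10e6,
                                     window = default_window(geometry,
                                                             sample_rate,
                                                             pulse, delay_s),
                                     attenuation_db_cm_mhz = 0,
                                     delay_s = 2e-5) {
  zs <- seq(z_range[1], z_range[2], by = step)
  truth <- tibble::tibble(
    position_id = seq_along(zs),
    x_mm = 0, y_mm = geometry$rho_mm + depth_mm, z_mm = zs, angle_deg = 0
  )
  new_foh_simulation(
    expand_scenes(truth, n_frames, seed), truth, geometry, pulse,
    sample_rate, window, snr_db, focal_depth_mm, attenuation_db_cm_mhz,
    delay_s, seed, kind = "elevation"
  )
}

#' Simulated needle-angle sweep experiment
#'
#' The tip is fixed on the central axis at `depth_mm` below the probe face
#' and the needle insertion angle is stepped through `angles`; the default is
#' thirteen angles equally spaced between 0 and 60 degrees.
#'
#' @inheritParams generate_grid_dataset
#' @param depth_mm Tip depth below the probe face (mm).
#' @param angles Needle insertion angles (degrees).
#' @param n_frames Frames per angle.
#' @return A `foh_simulation` (kind `"angle"`).
#' @export
generate_angle_sweep <- function(geometry = probe_geometry(),
                                 pulse = pulse_model(),
                                 depth_mm = 150,
                                 angles = seq(0, 60, by = 5),
                                 n_frames = 18,
                                 snr_db = 60,
                                 seed = 1,
                                 sample_rate = 10e6,
                                 window = default_window(geometry, sample_rate,
                                                         pulse, delay_s),
                                 focal_depth_mm = 15,
                                 attenuation_db_cm_mhz = 0,
                                 delay_s = 2e-5) {
  truth <- tibble::tibble(
    position_id = seq_along(angles),
    x_mm = 0, y_mm = geometry$rho_mm + depth_mm, z_mm = 0,
    angle_deg = angles
  )
  new_foh_simulation(
    expand_scenes(truth, n_frames, seed), truth, geometry, pulse,
    sample_rate, window, snr_db, focal_depth_mm, attenuation_db_cm_mhz,
    delay_s, seed, kind = "angle"
  )
}

#' Lay simulated frames out as a raw digitizer stream with triggers
#'
#' Concatenates the columns of the given frames into one continuous
#' hydrophone stream and builds the matching line-trigger and frame-gate
#' signals, for exercising the stream-segmentation stage end to end.
#'
#' @param frames List of [foh_frame()] objects with equal dimensions.
#' @param gap Samples between consecutive line windows and between frames.
#' @param trigger_high Trigger pulse amplitude (volts) and width 4 samples.
#' @return List with `foh_stream`, `stream` (a [trigger_stream()]) and
#'   `trigger_indices` (the sample index of each line trigger).
#' @export
simulate_raw_stream <- function(frames, gap = 16L, trigger_high = 5) {
  stopifnot(length(frames) >= 1, inherits(frames[[1]], "foh_frame"))
  window <- nrow(frames[[1]]$samples)
  n_lines <- ncol(frames[[1]]$samples)
  stride <- window + gap
  total <- length(frames) * (n_lines * stride + gap) + gap
  foh <- numeric(total)
  lt <- numeric(total)
  gate <- numeric(total)
  trig_idx <- integer(0)
  pos <- gap + 1L
  for (f in frames) {
    gate_start <- pos - gap %/% 2L
    for (j in seq_len(n_lines)) {
      foh[pos:(pos + window - 1L)] <- f$samples[, j]
      lt[pos:(pos + 3L)] <- trigger_high
      trig_idx <- c(trig_idx, pos)
      pos <- pos + stride
    }
    gate[gate_start:(pos - stride + window + gap %/% 2L)] <- trigger_high
    pos <- pos + gap
  }
  list(
    foh_stream = foh,
    stream = trigger_stream(lt, gate, frames[[1]]$sample_rate),
    trigger_indices = trig_idx
  )
}
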