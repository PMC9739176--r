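# Shared fixtures: a reduced probe (fewer lines, shallower depth) keeps
# per-frame FFT work small while preserving the geometry conventions.

small_geometry <- function(n_lines = 64) {
  probe_geometry(rho_mm = 68, fov_deg = 55, n_lines = n_lines,
                 sound_speed_mps = 1540, imaging_depth_mm = 200)
}

FS <- 10e6

# A frame containing the template waveform at given amplitudes/columns,
# starting at sample `at` in every active column.
template_frame <- function(template, geometry, amplitudes, at,
                           window = default_window(geometry, FS),
                           delay_s = 2e-5) {
  m <- matrix(0, window, geometry$n_lines)
  idx <- at:(at + length(template$waveform) - 1L)
  for (j in seq_along(amplitudes)) {
    if (amplitudes[j] != 0) m[idx, j] <- amplitudes[j] * template$waveform
  }
  foh_frame(m, FS, scan_line_angles(geometry),
            trigger_to_transmit_delay = delay_s)
}

# Noise-only frame at a given RMS.
noise_frame <- function(geometry, sd, seed,
                        window = default_window(geometry, FS)) {
  set.seed(seed)
  foh_frame(matrix(rnorm(window * geometry$n_lines, sd = sd), window),
            FS, scan_line_angles(geometry))
}

# Direct O(n^2) cross-correlation oracle for the matched filter:
# y[m] = sum_j x[m + j - 1] h[j].
direct_xcorr <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(m) {
    j <- seq_along(h)
    k <- m + j - 1
    ok <- k <= n
    sum(x[k[ok]] * h[j[ok]])
  }, numeric(1))
}
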