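#' Tracker options
#'
#' Tunable thresholds of the localisation pipeline.
#'
#' @param threshold_db Column-energy threshold relative to the maximum
#'   column (dB, negative); columns below it are zeroed before the
#'   centre-of-mass angle estimate.
#' @param snr_gate_db Frames with SNR below this are discarded (dB).
#' @param dynamic_range_db Centre-of-mass is used only when the maximum
#'   column energy exceeds the median column energy by at least this much
#'   (dB); otherwise the maximum-amplitude pixel is used.
#' @param toa_gate_pulse_lengths Half-width of the time-of-arrival analysis
#'   gate around the frame's global peak, in template lengths.
#' @param spread_form Form of the weighted angular-spread estimator, see
#'   [weighted_angle_spread()].
#' @return A list of class `tracker_options`.
#' @export
tracker_options <- function(threshold_db = -6, snr_gate_db = 12,
                            dynamic_range_db = 6, toa_gate_pulse_lengths = 8,
                            spread_form = c("corrected", "printed")) {
  structure(
    list(threshold_db = threshold_db, snr_gate_db = snr_gate_db,
         dynamic_range_db = dynamic_range_db,
         toa_gate_pulse_lengths = toa_gate_pulse_lengths,
         spread_form = match.arg(spread_form)),
    class = "tracker_options"
  )
}

#' Thresholded column energies of a processed frame
#'
#' Sums the squared samples of each column (times the sample interval, so
#' units are V^2 s) and zeroes columns whose energy falls below
#' `threshold_db` relative to the strongest column. The threshold stops
#' noisy scan lines biasing the centre-of-mass angle estimate.
#'
#' @param frame A processed (matched-filtered and enveloped) [foh_frame()].
#' @param threshold_db Relative threshold (dB, negative; default -6).
#' @return An object of class `column_energies` with fields `en` (V^2 s),
#'   `theta_deg`, `n` (columns), `n_prime` (columns surviving the
#'   threshold) and `degenerate` (all-zero frame).
#' @export
column_energies <- function(frame, threshold_db = -6) {
  stopifnot(inherits(frame, "foh_frame"))
  en <- colSums(frame$samples^2) / frame$sample_rate
  degenerate <- all(en == 0)
  if (!degenerate) {
    en[en < max(en) * 10^(threshold_db / 10)] <- 0
  }
  structure(
    list(en = en, theta_deg = frame$line_angles, n = length(en),
         n_prime = sum(en > 0), degenerate = degenerate),
    class = "column_energies"
  )
}

#' Energy-weighted mean scan-line angle
#'
#' The centre of mass of the thresholded column-energy distribution: the
#' tracker's estimate of the tip angle.
#'
#' @param ce A [column_energies()].
#' @return Weighted mean angle (degrees).
#' @export
weighted_mean_angle <- function(ce) {
  stopifnot(inherits(ce, "column_energies"))
  if (sum(ce$en) <= 0) stop("no signal: all column energies are zero",
                            call. = FALSE)
  sum(ce$theta_deg * ce$en) / sum(ce$en)
}

#' Energy-weighted angular spread
#'
#' Width of the thresholded energy distribution, used as the angular
#' uncertainty of the tracked tip. The default `"corrected"` form is the
#' weighted RMS deviation with a small-sample factor:
#' `sqrt(sum(e (th - thbar)^2) / sum(e)) * sqrt(Np / (Np - 1))`
#' where `Np` is the number of columns with nonzero energy. The
#' `"printed"` form divides the weighted sum of squares by
#' `Np (Np - 1) sum(e)` instead, the literal reading of the source formula
#' whose typography is ambiguous; it is provided for comparison. Both
#' return 0 when a single column holds all the energy.
#'
#' @param ce A [column_energies()].
#' @param theta_bar Weighted mean angle (degrees), from
#'   [weighted_mean_angle()].
#' @param form `"corrected"` (default) or `"printed"`.
#' @return Angular spread (degrees); 0 with attribute `degenerate = TRUE`
#'   when fewer than two columns carry energy.
#' @export
weighted_angle_spread <- function(ce, theta_bar,
                                  form = c("corrected", "printed")) {
  stopifnot(inherits(ce, "column_energies"))
  form <- match.arg(form)
  np <- ce$n_prime
  if (np < 2) return(structure(0, degenerate = TRUE))
  wss <- sum(ce$en * (ce$theta_deg - theta_bar)^2)
  if (form == "corrected") {
    sqrt(wss / sum(ce$en)) * sqrt(np / (np - 1))
  } else {
    sqrt(wss / (np * (np - 1) * sum(ce$en)))
  }
}

#' Pulse time of arrival from cumulative energy
#'
#' Implements the 10--90% cumulative-energy onset rule: within an analysis
#' gate around the waveform's peak, the cumulative integral of the squared
#' waveform is formed and the times `t0.1` and `t0.9` at which it reaches
#' 10% and 90% of its final value are located by linear interpolation.
#' The pulse duration is `1.25 * dt` with `dt = t0.9 - t0.1`, and the pulse
#' start is `t0.1 - 0.125 * dt`. Sample `i` is treated as covering the
#' interval `[(i-1)/fs, i/fs)`, which makes the rule exact for a
#' rectangular envelope starting at a sample boundary.
#'
#' @param waveform Numeric vector: one processed column.
#' @param sample_rate Sampling rate (Hz).
#' @param gate_halfwidth Samples either side of the global absolute peak to
#'   include (default `Inf`: the whole waveform). Gating prevents the
#'   noise floor inflating the cumulative integral.
#' @return List with `t_start` and `delta_t` (seconds, relative to the
#'   first sample of the waveform).
#' @export
time_of_arrival <- function(waveform, sample_rate, gate_halfwidth = Inf) {
  e_all <- waveform^2
  if (sum(e_all) == 0) stop("no signal: waveform has zero energy",
                            call. = FALSE)
  if (is.finite(gate_halfwidth)) {
    peak <- which.max(abs(waveform))
    i1 <- max(1L, peak - as.integer(gate_halfwidth))
    i2 <- min(length(waveform), peak + as.integer(gate_halfwidth))
  } else {
    i1 <- 1L
    i2 <- length(waveform)
  }
  e <- e_all[i1:i2]
  total <- sum(e)
  if (total == 0) stop("no signal inside the analysis gate", call. = FALSE)
  ce <- c(0, cumsum(e))
  cross <- function(q) {
    k <- findInterval(q, ce, left.open = TRUE)  # ce[k] < q <= ce[k + 1]
    if (k >= length(ce)) k <- length(ce) - 1L
    frac <- (q - ce[k]) / (ce[k + 1] - ce[k])
    (i1 - 1 + k - 1 + frac) / sample_rate
  }
  t01 <- cross(0.1 * total)
  t09 <- cross(0.9 * total)
  dt <- t09 - t01
  list(t_start = t01 - 0.125 * dt, delta_t = dt)
}

#' Radial position from time of arrival
#'
#' Converts a pulse start time to range: `r = c (t - delay) + rho`, with the
#' radial uncertainty taken as the pulse length `sigma_r = 1.25 c dt`.
#'
#' @param t_start Pulse start time (s, relative to the line trigger).
#' @param delta_t 10--90% cumulative-energy interval (s).
#' @param geometry A [probe_geometry()].
#' @param delay_s Trigger-to-transmit delay of the imaging system (s).
#' @return List with `r_mm` and `sigma_r_mm`.
#' @export
radial_position <- function(t_start, delta_t, geometry, delay_s = 0) {
  stopifnot(inherits(geometry, "probe_geometry"))
  if (t_start < delay_s) {
    stop("pre-transmit: pulse start precedes the transmission", call. = FALSE)
  }
  c_mm <- geometry$sound_speed_mps * 1000
  list(r_mm = c_mm * (t_start - delay_s) + geometry$rho_mm,
       sigma_r_mm = 1.25 * c_mm * delta_t)
}

# The cumulative-energy onset rule applied to a matched-filtered envelope
# reads the onset of the symmetric correlation envelope, which leads the
# true pulse start by a fixed, template-dependent amount. Measure that
# offset once by running the template itself through the same pipeline.
template_toa_offset <- function(template, options = tracker_options()) {
  len <- length(template$waveform)
  k0 <- len + 1L
  col <- numeric(next_pow2(4L * len))
  col[k0:(k0 + len - 1L)] <- template$waveform
  f <- foh_frame(matrix(col, ncol = 1), template$sample_rate, 0)
  proc <- preprocess_frame(f, template)
  toa <- time_of_arrival(proc$samples[, 1], template$sample_rate,
                         gate_halfwidth = options$toa_gate_pulse_lengths * len)
  toa$t_start - (k0 - 1) / template$sample_rate
}

new_polar_estimate <- function(r_mm = NA_real_, theta_deg = NA_real_,
                               sigma_r_mm = NA_real_,
                               sigma_theta_deg = NA_real_,
                               snr_db = NA_real_, valid = FALSE,
                               method = NA_character_,
                               n_prime = NA_integer_) {
  structure(
    list(r_mm = r_mm, theta_deg = theta_deg, sigma_r_mm = sigma_r_mm,
         sigma_theta_deg = sigma_theta_deg, snr_db = snr_db, valid = valid,
         method = method, n_prime = n_prime),
    class = "polar_estimate"
  )
}

#' @export
print.polar_estimate <- function(x, ...) {
  if (!x$valid) {
    cat("<polar_estimate> invalid (gated out or no signal)\n")
  } else {
    cat(sprintf(
      "<polar_estimate> r = %.2f +/- %.2f mm, theta = %.3f +/- %.3f deg (%s, SNR %.1f dB)\n",
      x$r_mm, x$sigma_r_mm, x$theta_deg, x$sigma_theta_deg, x$method, x$snr_db
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a polar estimate into a one-row tibble
#'
#' @param x A `polar_estimate`.
#' @param ... Unused.
#' @export
tidy.polar_estimate <- function(x, ...) {
  tibble::tibble(
    r_mm = x$r_mm, theta_deg = x$theta_deg, sigma_r_mm = x$sigma_r_mm,
    sigma_theta_deg = x$sigma_theta_deg, snr_db = x$snr_db, valid = x$valid,
    method = x$method, n_prime = x$n_prime
  )
}

#' Localise the needle tip in one FOH frame
#'
#' Full tracking pipeline for one frame: matched filter, envelope detection,
#' SNR gating, thresholded column energies, angle by energy centre of mass
#' (or the maximum-amplitude pixel when the column-energy dynamic range is
#' below `dynamic_range_db`), and range from the time of arrival of the
#' maximum-energy column with the template's onset offset compensated.
#' Data-content problems (pure noise, zero signal) yield an invalid
#' estimate, never an error.
#'
#' @param frame A raw [foh_frame()].
#' @param template A [pulse_template()].
#' @param geometry A [probe_geometry()].
#' @param noise A [noise_level()] measured on *processed* noise frames, or
#'   `NULL` to skip the SNR gate.
#' @param options A [tracker_options()].
#' @param delay_s Trigger-to-transmit delay (s); defaults to the frame's.
#' @param toa_offset_s Template onset offset (s); computed from the
#'   template when `NULL`.
#' @return A `polar_estimate`.
#' @export
localise_frame <- function(frame, template, geometry, noise = NULL,
                           options = tracker_options(),
                           delay_s = frame$trigger_to_transmit_delay,
                           toa_offset_s = NULL) {
  stopifnot(inherits(frame, "foh_frame"), inherits(geometry, "probe_geometry"))
  tryCatch({
    proc <- preprocess_frame(frame, template)
    snr <- if (is.null(noise)) Inf else frame_snr(proc, noise)
    if (!is.null(noise) && snr < options$snr_gate_db) {
      est <- new_polar_estimate(snr_db = snr, valid = FALSE)
      return(est)
    }
    ce <- column_energies(proc, options$threshold_db)
    if (ce$degenerate) {
      return(new_polar_estimate(snr_db = snr, valid = FALSE))
    }
    raw_en <- colSums(proc$samples^2)
    dyn_ok <- max(raw_en) >=
      stats::median(raw_en) * 10^(options$dynamic_range_db / 10)
    if (dyn_ok) {
      theta <- weighted_mean_angle(ce)
      method <- "centre_of_mass"
    } else {
      peak <- arrayInd(which.max(proc$samples), dim(proc$samples))
      theta <- frame$line_angles[peak[1, 2]]
      method <- "max_pixel"
    }
    sigma_theta <- weighted_angle_spread(ce, weighted_mean_angle(ce),
                                         form = options$spread_form)
    toa_col <- which.max(ce$en)  # ties: lowest column index
    if (is.null(toa_offset_s)) {
      toa_offset_s <- template_toa_offset(template, options)
    }
    gate <- options$toa_gate_pulse_lengths * length(template$waveform)
    toa <- time_of_arrival(proc$samples[, toa_col], frame$sample_rate,
                           gate_halfwidth = gate)
    rad <- radial_position(toa$t_start - toa_offset_s, toa$delta_t,
                           geometry, delay_s)
    in_fan <- abs(theta) <= geometry$fov_deg / 2 + 1 && rad$r_mm >= 0
    new_polar_estimate(
      r_mm = rad$r_mm, theta_deg = theta, sigma_r_mm = rad$sigma_r_mm,
      sigma_theta_deg = as.numeric(sigma_theta), snr_db = snr,
      valid = in_fan, method = method, n_prime = ce$n_prime
    )
  }, error = function(e) new_polar_estimate(valid = FALSE))
}

#' Track every frame of a simulated dataset
#'
#' Runs [localise_frame()] and [to_cartesian()] over all frames of a
#' `foh_simulation`, synthesising each frame on demand. When the dataset is
#' noisy, a processed noise level is measured once from `n_noise_frames`
#' noise-only frames generated at the dataset's common noise RMS, and the
#' SNR gate is applied with it.
#'
#' @param sim A `foh_simulation`.
#' @param template A [pulse_template()]; defaults to the pulse model's
#'   zero-angle pulse.
#' @param options A [tracker_options()].
#' @param n_noise_frames Noise frames used to measure the noise level.
#' @return A tibble with one row per frame: `position_id`, `frame`, the
#'   polar estimate columns, the scan-converted `x_mm`, `y_mm`,
#'   `sigma_x_mm`, `sigma_y_mm`, `cov_xy_mm2`, `snr_db`, `valid`, `method`.
#' @export
track_frames <- function(sim, template = default_template(sim$pulse,
                                                          sim$sample_rate),
                         options = tracker_options(), n_noise_frames = 2) {
  stopifnot(inherits(sim, "foh_simulation"))
  noise <- NULL
  if (is.finite(sim$snr_db) && sim$noise_rms > 0) {
    noise_frames <- lapply(seq_len(n_noise_frames), function(k) {
      m <- with_seed((sim$seed + 900000 + k) %% .Machine$integer.max,
                     matrix(stats::rnorm(sim$window * sim$geometry$n_lines,
                                         sd = sim$noise_rms),
                            nrow = sim$window))
      preprocess_frame(
        foh_frame(m, sim$sample_rate, scan_line_angles(sim$geometry)),
        template
      )
    })
    noise <- noise_level(noise_frames)
  }
  offset <- template_toa_offset(template, options)
  rows <- lapply(seq_len(nrow(sim$scenes)), function(i) {
    est <- localise_frame(sim_frame(sim, i), template, sim$geometry,
                          noise = noise, options = options,
                          delay_s = sim$delay_s, toa_offset_s = offset)
    cart <- to_cartesian(est)
    tibble::tibble(
      position_id = sim$scenes$position_id[i],
      frame = sim$scenes$frame[i],
      r_mm = est$r_mm, theta_deg = est$theta_deg,
      sigma_r_mm = est$sigma_r_mm, sigma_theta_deg = est$sigma_theta_deg,
      x_mm = cart$x_mm, y_mm = cart$y_mm,
      sigma_x_mm = cart$sigma_x_mm, sigma_y_mm = cart$sigma_y_mm,
      cov_xy_mm2 = cart$cov[1, 2],
      snr_db = est$snr_db, valid = est$valid, method = est$method
    )
  })
  dplyr::bind_rows(rows)
}
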