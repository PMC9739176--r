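#' Matched-filter template
#'
#' The reference pulse the matched filter correlates each waveform against.
#' The default template used throughout the package is the simulator's
#' zero-angle pulse (main frequency band only), mirroring a template
#' synthesised from observed pulses; users tracking real data can supply a
#' measured waveform instead.
#'
#' @param waveform Numeric vector (volts) with nonzero energy.
#' @param sample_rate Sampling rate (Hz).
#' @return An object of class `pulse_template`.
#' @export
pulse_template <- function(waveform, sample_rate) {
  waveform <- as.numeric(waveform)
  if (length(waveform) == 0 || all(waveform == 0)) {
    stop("template must have nonzero energy", call. = FALSE)
  }
  stopifnot("sample_rate must be > 0" = sample_rate > 0)
  structure(list(waveform = waveform, sample_rate = sample_rate),
            class = "pulse_template")
}

#' @rdname pulse_template
#' @param model A [pulse_model()]; the template is its 0-degree pulse.
#' @export
default_template <- function(model = pulse_model(), sample_rate = 10e6) {
  zero_lf <- pulse_model(model$f0, model$fractional_bandwidth,
                         low_freq_fraction = function(a) 0 * a,
                         low_freq_f = model$low_freq_f)
  w <- synthesize_pulse(zero_lf, sample_rate, needle_angle = 0)
  pulse_template(as.numeric(w), sample_rate)
}

#' Read or write a matched-filter template file
#'
#' Single-column numeric text with a `# sample_rate_hz:` header line.
#'
#' @param path File path.
#' @return `read_template()` returns a [pulse_template()].
#' @export
read_template <- function(path) {
  header <- readLines(path, n = 1)
  sr <- as.numeric(sub("^#\\s*sample_rate_hz:\\s*", "", header))
  if (is.na(sr)) stop("template file missing sample_rate header", call. = FALSE)
  pulse_template(utils::read.table(path, skip = 1)[[1]], sr)
}

#' @rdname read_template
#' @param template A [pulse_template()].
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "pulse_template"))
  writeLines(c(sprintf("# sample_rate_hz: %.10g", template$sample_rate),
               format(template$waveform, digits = 17)), path)
  invisible(path)
}

# Next power of two >= n (FFT-friendly padding).
next_pow2 <- function(n) 2^ceiling(log2(n))

# Next integer >= n with no prime factor beyond 5, so per-column FFTs stay
# fast for arbitrary window lengths.
next_fast_len <- function(n) {
  m <- as.integer(ceiling(n))
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

#' Matched filtering of an FOH frame
#'
#' Cross-correlates each column of the frame with the template (equivalently,
#' convolves with its time reverse), computed in the frequency domain with
#' zero padding. The output has the same length as the input, and the lag is
#' aligned so that a column equal to the template starting at sample `k`
#' peaks at sample `k` (group delay compensated), keeping downstream
#' time-of-arrival estimates unbiased.
#'
#' @param frame A [foh_frame()].
#' @param template A [pulse_template()] at the same sample rate.
#' @return A [foh_frame()] of matched-filter outputs.
#' @export
matched_filter <- function(frame, template) {
  stopifnot(inherits(frame, "foh_frame"), inherits(template, "pulse_template"))
  if (frame$sample_rate != template$sample_rate) {
    stop("frame and template sample rates differ", call. = FALSE)
  }
  x <- frame$samples
  h <- template$waveform
  n <- nrow(x)
  L <- next_pow2(n + length(h))
  H <- stats::fft(c(h, numeric(L - length(h))))
  X <- stats::mvfft(rbind(x, matrix(0, L - n, ncol(x))))
  # correlation: y[m] = sum_j x[m + j - 1] h[j]
  y <- Re(stats::mvfft(X * Conj(H), inverse = TRUE)) / L
  out <- frame
  out$samples <- y[seq_len(n), , drop = FALSE]
  out
}

# Analytic-signal magnitude per column: suppress negative frequencies in the
# FFT, double positive ones, and take the modulus of the inverse transform.
analytic_envelope <- function(x) {
  n <- nrow(x)
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[1] <- 1; mult[n / 2 + 1] <- 1; mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1; mult[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x) * mult
  Mod(stats::mvfft(X, inverse = TRUE)) / n
}

#' Envelope detection of an FOH frame
#'
#' Per-column magnitude of the analytic signal (Hilbert-transform envelope):
#' non-negative and, for band-limited pulses, ripple-free, recovering the
#' modulating window of a windowed sinusoid away from the edges.
#'
#' @param frame A [foh_frame()].
#' @return A [foh_frame()] of envelopes.
#' @export
envelope <- function(frame) {
  stopifnot(inherits(frame, "foh_frame"))
  out <- frame
  out$samples <- analytic_envelope(frame$samples)
  out
}

#' Preprocess a frame: matched filter then envelope
#'
#' @inheritParams matched_filter
#' @return A [foh_frame()] of processed (matched-filtered and
#'   envelope-detected) waveforms.
#' @export
preprocess_frame <- function(frame, template) {
  envelope(matched_filter(frame, template))
}

#' Common noise level from noise-only frames
#'
#' Per the common-noise-level convention: the RMS voltage of every waveform
#' (column) in the supplied noise frames is computed, then averaged; the
#' standard deviation across waveforms is kept as a check that the noise
#' level does not vary materially.
#'
#' @param noise_frames A [foh_frame()] or list of them (noise-only
#'   acquisitions, raw or processed — use the same stage as the frames whose
#'   SNR will be measured).
#' @return An object of class `noise_level` with fields `rms`,
#'   `per_waveform_rms_std`, `n_waveforms` and `degenerate` (all-zero input).
#' @export
noise_level <- function(noise_frames) {
  if (inherits(noise_frames, "foh_frame")) noise_frames <- list(noise_frames)
  stopifnot(length(noise_frames) >= 1)
  rms_per <- unlist(lapply(noise_frames, function(f) {
    sqrt(colMeans(f$samples^2))
  }))
  structure(
    list(rms = mean(rms_per),
         per_waveform_rms_std = stats::sd(rms_per),
         n_waveforms = length(rms_per),
         degenerate = mean(rms_per) == 0),
    class = "noise_level"
  )
}

#' Frame signal-to-noise ratio
#'
#' Peak absolute voltage in the frame divided by the common noise RMS,
#' in decibels: `20 log10(peak / rms)`.
#'
#' @param frame A [foh_frame()] (same processing stage as the noise level).
#' @param noise A [noise_level()].
#' @return SNR in dB.
#' @export
frame_snr <- function(frame, noise) {
  stopifnot(inherits(frame, "foh_frame"), inherits(noise, "noise_level"))
  if (noise$degenerate || noise$rms <= 0) return(Inf)
  20 * log10(max(abs(frame$samples)) / noise$rms)
}

#' SNR gate for a frame
#'
#' Frames whose SNR falls below the threshold yield no position estimate.
#' The default threshold of 12 dB rejects processed noise-only frames (whose
#' envelope peak-to-RMS ratio stays below ~11 dB with very high probability)
#' while passing low-signal tissue frames around 30 dB with a wide margin.
#'
#' @inheritParams frame_snr
#' @param threshold_db Gate threshold (dB).
#' @return Logical: `TRUE` if the frame is valid.
#' @export
gate_frame <- function(frame, noise, threshold_db = 12) {
  frame_snr(frame, noise) >= threshold_db
}
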