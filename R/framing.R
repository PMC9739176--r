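#' FOH frame: per-scan-line hydrophone waveforms for one B-mode frame
#'
#' One frame of fibre-optic hydrophone data: a numeric matrix with one column
#' per scan line (ordered by increasing scan-line angle) and one row per time
#' sample, where time zero of each column is the line-trigger instant of the
#' corresponding ultrasound transmission.
#'
#' @param samples Numeric matrix, `n_samples x n_lines` (volts).
#' @param sample_rate Sampling rate (Hz).
#' @param line_angles Scan-line angle per column (degrees), strictly
#'   increasing, length `n_lines`.
#' @param frame_index Integer index of the frame within its acquisition.
#' @param trigger_to_transmit_delay Delay between the line trigger and the
#'   actual ultrasound transmission (seconds).
#' @return An object of class `foh_frame`.
#' @export
foh_frame <- function(samples, sample_rate, line_angles,
                      frame_index = 1L, trigger_to_transmit_delay = 0) {
  samples <- as.matrix(samples)
  stopifnot(
    "samples must be numeric" = is.numeric(samples),
    "samples must have > 0 rows" = nrow(samples) > 0,
    "sample_rate must be > 0" = sample_rate > 0,
    "one angle per column required" = length(line_angles) == ncol(samples)
  )
  if (is.unsorted(line_angles, strictly = TRUE)) {
    stop("line_angles must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sample_rate = as.numeric(sample_rate),
      line_angles = as.numeric(line_angles),
      frame_index = as.integer(frame_index),
      trigger_to_transmit_delay = as.numeric(trigger_to_transmit_delay)
    ),
    class = "foh_frame"
  )
}

#' @export
print.foh_frame <- function(x, ...) {
  cat(sprintf(
    "<foh_frame #%d> %d samples x %d lines @ %g MHz, angles [%0.2f, %0.2f] deg\n",
    x$frame_index, nrow(x$samples), ncol(x$samples), x$sample_rate / 1e6,
    min(x$line_angles), max(x$line_angles)
  ))
  invisible(x)
}

#' Trigger stream: line and frame synchronisation signals
#'
#' The line trigger is a voltage pulse synchronised to each ultrasound
#' transmission; the frame gate is a signal that is high for the duration of
#' each B-mode frame (the integrated line trigger). Both are sampled at the
#' digitizer rate alongside the hydrophone signal.
#'
#' @param line_trigger Numeric vector (volts).
#' @param frame_gate Numeric vector (volts), same length.
#' @param sample_rate Sampling rate (Hz).
#' @return An object of class `trigger_stream`.
#' @export
trigger_stream <- function(line_trigger, frame_gate, sample_rate) {
  stopifnot(
    "equal lengths required" = length(line_trigger) == length(frame_gate),
    "sample_rate must be > 0" = sample_rate > 0
  )
  structure(
    list(line_trigger = as.numeric(line_trigger),
         frame_gate = as.numeric(frame_gate),
         sample_rate = as.numeric(sample_rate)),
    class = "trigger_stream"
  )
}

#' Detect line-trigger edges
#'
#' Finds rising edges of the line-trigger signal: sample indices where the
#' voltage crosses `threshold` upwards. Edges closer together than
#' `min_gap` samples are debounced (only the first is kept); by default the
#' gap is half the median inter-trigger interval of the raw crossings, which
#' suppresses single-sample glitches inside a trigger pulse.
#'
#' @param stream A [trigger_stream()].
#' @param threshold Crossing threshold (volts).
#' @param min_gap Minimum inter-trigger gap in samples, or `NULL` for the
#'   default of `0.5 *` the median raw inter-trigger interval.
#' @return Integer vector of strictly increasing sample indices (possibly
#'   empty).
#' @export
detect_line_triggers <- function(stream, threshold = 0.5, min_gap = NULL) {
  stopifnot(inherits(stream, "trigger_stream"))
  v <- stream$line_trigger
  if (length(v) < 2) return(integer(0))
  raw <- which(v[-length(v)] < threshold & v[-1] >= threshold) + 1L
  if (length(raw) <= 1) return(raw)
  if (is.null(min_gap)) {
    min_gap <- 0.5 * stats::median(diff(raw))
  }
  keep <- raw[1]
  for (i in raw[-1]) {
    if (i - keep[length(keep)] >= min_gap) keep <- c(keep, i)
  }
  as.integer(keep)
}

# High intervals of the frame gate as a 2-column matrix (start, end), using
# the same rising/falling threshold; partial intervals at the stream edges
# are dropped because the frames they hold are incomplete.
frame_gate_intervals <- function(gate, threshold = 0.5) {
  high <- gate >= threshold
  d <- diff(c(FALSE, high, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  keep <- starts > 1 & ends < length(gate)
  cbind(start = starts[keep], end = ends[keep])
}

#' Segment a hydrophone stream into FOH frames
#'
#' Splits a continuous digitizer voltage stream into [foh_frame()] objects
#' using the line-trigger edges grouped by frame-gate high intervals. Each
#' column of a frame is `window` consecutive samples of the stream starting
#' at its line-trigger index. Gate intervals that do not contain exactly
#' `n_lines` triggers, or whose last window would run past the end of the
#' stream, are flagged malformed and skipped with a warning.
#'
#' @param foh_stream Numeric vector: the hydrophone voltage stream.
#' @param stream A [trigger_stream()] sampled at the same rate.
#' @param n_lines Number of transmissions per frame.
#' @param window Samples acquired per scan line.
#' @param line_angles Scan-line angles attached to each frame (degrees);
#'   defaults to evenly spaced placeholder indices when unknown.
#' @param threshold Trigger/gate detection threshold (volts).
#' @param trigger_to_transmit_delay Stored on each frame (seconds).
#' @return List of [foh_frame()] objects, `frame_index` numbered by gate
#'   interval.
#' @export
segment_frames <- function(foh_stream, stream, n_lines, window,
                           line_angles = NULL, threshold = 0.5,
                           trigger_to_transmit_delay = 0) {
  stopifnot(
    inherits(stream, "trigger_stream"),
    length(foh_stream) == length(stream$line_trigger),
    n_lines >= 1, window >= 1
  )
  if (is.null(line_angles)) line_angles <- seq_len(n_lines)
  triggers <- detect_line_triggers(stream, threshold)
  intervals <- frame_gate_intervals(stream$frame_gate, threshold)
  frames <- list()
  for (k in seq_len(nrow(intervals))) {
    inside <- triggers[triggers >= intervals[k, "start"] &
                       triggers <= intervals[k, "end"]]
    if (length(inside) != n_lines) {
      warning(sprintf(
        "frame %d malformed: %d line triggers in gate interval (expected %d); skipped",
        k, length(inside), n_lines
      ), call. = FALSE)
      next
    }
    if (max(inside) + window - 1L > length(foh_stream)) {
      warning(sprintf("frame %d truncated at stream edge; dropped", k),
              call. = FALSE)
      next
    }
    cols <- vapply(inside, function(i) foh_stream[i:(i + window - 1L)],
                   numeric(window))
    frames[[length(frames) + 1L]] <- foh_frame(
      cols, stream$sample_rate, line_angles, frame_index = k,
      trigger_to_transmit_delay = trigger_to_transmit_delay
    )
  }
  frames
}
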