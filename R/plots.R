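#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FOH frame as a time-angle image
#'
#' Absolute sample amplitude versus scan-line angle and time, the standard
#' way to look at one frame's energy distribution.
#'
#' @param object A [foh_frame()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.foh_frame <- function(object, ...) {
  df <- tidyr::expand_grid(
    sample = seq_len(nrow(object$samples)),
    line = seq_len(ncol(object$samples))
  )
  df$t_us <- (df$sample - 1) / object$sample_rate * 1e6
  df$angle_deg <- object$line_angles[df$line]
  df$amplitude <- abs(as.vector(object$samples))
  ggplot2::ggplot(df, ggplot2::aes(.data$angle_deg, .data$t_us,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "scan-line angle (deg)", y = "time (µs)",
                  fill = "|V|",
                  title = sprintf("FOH frame #%d", object$frame_index)) +
    ggplot2::theme_minimal()
}

#' Spatial map of a per-location metric
#'
#' Plots a per-location metric (error or repeatability magnitude by
#' default) at its true position in the imaging plane, with depth
#' increasing downwards as in a B-mode display.
#'
#' @param metrics Tibble from [position_metrics()].
#' @param metric Column to map.
#' @return A ggplot.
#' @export
plot_metric_field <- function(metrics, metric = "e_mag_mm") {
  ggplot2::ggplot(metrics, ggplot2::aes(.data$truth_x_mm, .data$truth_y_mm,
                                        colour = .data[[metric]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral x (mm)", y = "axial y (mm)",
                  colour = metric) +
    ggplot2::theme_minimal()
}

#' Out-of-plane sweep curves
#'
#' SNR, displacement and repeatability versus elevational position, the
#' standard panels of an out-of-plane tracking assessment.
#'
#' @param curves Tibble from [elevation_analysis()].
#' @return A ggplot (facetted).
#' @export
plot_elevation_curves <- function(curves) {
  long <- tidyr::pivot_longer(
    curves, c("snr_db", "disp_x_mm", "disp_y_mm", "rep_x_mm", "rep_y_mm"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$z_mm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "elevational position z (mm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Raw and processed amplitude versus needle angle
#'
#' @param amplitudes Tibble from [angle_analysis()].
#' @return A ggplot.
#' @export
plot_angle_amplitude <- function(amplitudes) {
  long <- tidyr::pivot_longer(
    amplitudes, c("raw_amp", "proc_amp"),
    names_to = "stage", values_to = "amplitude"
  )
  long$stage <- ifelse(long$stage == "raw_amp", "raw", "processed")
  ggplot2::ggplot(long, ggplot2::aes(.data$angle_deg, .data$amplitude,
                                     colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "needle insertion angle (deg)",
                  y = "peak amplitude (V)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Glance at a tracked-frames table
#'
#' One-row summary of a [track_frames()] result: frame counts, validity
#' rate and median uncertainties.
#'
#' @param x Tibble from [track_frames()].
#' @param ... Unused.
#' @export
glance_track <- function(x, ...) {
  v <- x[x$valid, ]
  tibble::tibble(
    n_frames = nrow(x),
    n_valid = nrow(v),
    valid_rate = nrow(v) / nrow(x),
    median_snr_db = stats::median(v$snr_db),
    median_sigma_r_mm = stats::median(v$sigma_r_mm),
    median_sigma_theta_deg = stats::median(v$sigma_theta_deg)
  )
}
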