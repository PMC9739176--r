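#' Polar covariance matrix of a tracked position
#'
#' Builds the 2x2 covariance of the tracked position in the local
#' radial/tangential frame aligned to the tip angle: variance `sigma_r^2`
#' along the radial direction and `(r tan(sigma_theta))^2` along the
#' tangential direction, with zero cross terms.
#'
#' @param sigma_r_mm Radial uncertainty (mm).
#' @param sigma_theta_deg Angular uncertainty (degrees, `< 90`).
#' @param r_mm Radial position (mm, `> 0`).
#' @return 2x2 covariance matrix (mm^2), radial component first.
#' @export
polar_covariance <- function(sigma_r_mm, sigma_theta_deg, r_mm) {
  stopifnot("r_mm must be > 0" = r_mm > 0,
            "sigma_theta_deg must be < 90" = sigma_theta_deg < 90)
  diag(c(sigma_r_mm^2, (r_mm * tan(sigma_theta_deg * pi / 180))^2))
}

#' Rotate a covariance matrix
#'
#' `K_out = R K R^T` with the standard rotation matrix
#' `R = [[cos phi, -sin phi], [sin phi, cos phi]]`. Symmetry and the trace
#' (total variance) are preserved.
#'
#' @param K 2x2 covariance matrix.
#' @param phi_deg Rotation angle (degrees).
#' @return Rotated 2x2 covariance matrix.
#' @export
rotate_covariance <- function(K, phi_deg) {
  stopifnot(is.matrix(K), all(dim(K) == c(2, 2)))
  phi <- phi_deg * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  K2 <- R %*% K %*% t(R)
  (K2 + t(K2)) / 2
}

new_cartesian_estimate <- function(x_mm = NA_real_, y_mm = NA_real_,
                                   cov = matrix(NA_real_, 2, 2),
                                   valid = FALSE) {
  structure(
    list(x_mm = x_mm, y_mm = y_mm, cov = cov,
         sigma_x_mm = sqrt(cov[1, 1]), sigma_y_mm = sqrt(cov[2, 2]),
         valid = valid),
    class = "cartesian_estimate"
  )
}

#' @export
print.cartesian_estimate <- function(x, ...) {
  if (!x$valid) {
    cat("<cartesian_estimate> invalid\n")
  } else {
    cat(sprintf(
      "<cartesian_estimate> x = %.2f +/- %.2f mm, y = %.2f +/- %.2f mm\n",
      x$x_mm, x$sigma_x_mm, x$y_mm, x$sigma_y_mm
    ))
  }
  invisible(x)
}

#' Tidy a Cartesian estimate into a one-row tibble
#'
#' @param x A `cartesian_estimate`.
#' @param ... Unused.
#' @export
tidy.cartesian_estimate <- function(x, ...) {
  tibble::tibble(
    x_mm = x$x_mm, y_mm = x$y_mm, sigma_x_mm = x$sigma_x_mm,
    sigma_y_mm = x$sigma_y_mm, cov_xy_mm2 = x$cov[1, 2], valid = x$valid
  )
}

#' Scan conversion of a polar estimate with covariance propagation
#'
#' Converts a tracked polar position to Cartesian image coordinates
#' (`x = r sin(theta)`, `y = r cos(theta)`) and propagates the radial and
#' angular uncertainties: the radial/tangential covariance from
#' [polar_covariance()] is rotated into the (x, y) axes by `90 - theta`
#' degrees, so that on-axis (`theta = 0`) the radial uncertainty maps
#' entirely to the axial `y` axis. Invalid estimates stay invalid.
#'
#' @param est A `polar_estimate` from [localise_frame()].
#' @return A `cartesian_estimate` with fields `x_mm`, `y_mm`, `cov` (2x2,
#'   mm^2), `sigma_x_mm`, `sigma_y_mm` and `valid`.
#' @export
to_cartesian <- function(est) {
  stopifnot(inherits(est, "polar_estimate"))
  if (!isTRUE(est$valid) || !is.finite(est$r_mm)) {
    return(new_cartesian_estimate())
  }
  pos <- polar_to_cartesian(est$r_mm, est$theta_deg)
  K_rs <- polar_covariance(est$sigma_r_mm, est$sigma_theta_deg, est$r_mm)
  K_xy <- rotate_covariance(K_rs, 90 - est$theta_deg)
  new_cartesian_estimate(pos$x, pos$y, K_xy, valid = TRUE)
}

#' Pixel calibration of a B-mode image
#'
#' Recovers the pixel size and the pixel coordinates of the probe's centre
#' of curvature (the fan apex) from a single grey-scale B-mode frame,
#' given the configured imaging depth. The fan sector is segmented by an
#' intensity threshold at 1% of the maximum; points on the two straight fan
#' edges are extracted row-wise from the upper part of the sector and fitted
#' with total-least-squares lines whose intersection is the apex; the pixel
#' size follows from the radial extent of the sector, which spans the
#' imaging depth.
#'
#' @param image Numeric matrix in `[0, 1]` (rows x cols, grey levels), fan
#'   on a black background.
#' @param imaging_depth_mm Configured imaging depth (mm).
#' @return An object of class `image_calibration`: `pixel_size_mm` (mm per
#'   pixel, isotropic), `apex_px` (row, col; may lie above the image),
#'   `image_size` and `edge_residual_px` diagnostics.
#' @export
calibrate_image <- function(image, imaging_depth_mm) {
  stopifnot(is.matrix(image), imaging_depth_mm > 0)
  mask <- image > 0.01 * max(image)
  if (!any(mask)) stop("calibration error: no fan detected", call. = FALSE)
  rows_with <- which(rowSums(mask) > 0)
  # use the upper 60% of the sector, where the row-wise extremes lie on the
  # straight edges rather than the bottom arc
  band <- rows_with[seq_len(max(2, floor(0.6 * length(rows_with))))]
  left <- vapply(band, function(r) which(mask[r, ])[1], numeric(1))
  right <- vapply(band, function(r) rev(which(mask[r, ]))[1], numeric(1))
  fit_tls <- function(rr, cc) {
    # principal axis through the points; return as c(col0, dcol/drow)
    pc <- stats::prcomp(cbind(rr, cc))
    d <- pc$rotation[, 1]
    if (abs(d[1]) < 1e-12) stop("calibration error: degenerate fan edge",
                                call. = FALSE)
    list(r0 = mean(rr), c0 = mean(cc), slope = unname(d[2] / d[1]))
  }
  fl <- fit_tls(band, left)
  fr <- fit_tls(band, right)
  if (abs(fl$slope - fr$slope) < 1e-9) {
    stop("calibration error: fan edges are parallel", call. = FALSE)
  }
  # intersection of c = c0 + slope (r - r0) for the two edges
  apex_row <- ((fr$c0 - fr$slope * fr$r0) - (fl$c0 - fl$slope * fl$r0)) /
    (fl$slope - fr$slope)
  apex_col <- fl$c0 + fl$slope * (apex_row - fl$r0)
  idx <- which(mask, arr.ind = TRUE)
  dist <- sqrt((idx[, 1] - apex_row)^2 + (idx[, 2] - apex_col)^2)
  r_outer <- stats::quantile(dist, 0.999, names = FALSE)
  r_inner <- stats::quantile(dist, 0.001, names = FALSE)
  if (r_outer - r_inner < 2) {
    stop("calibration error: fan has no radial extent", call. = FALSE)
  }
  resid <- c(left - (fl$c0 + fl$slope * (band - fl$r0)),
             right - (fr$c0 + fr$slope * (band - fr$r0)))
  structure(
    list(pixel_size_mm = imaging_depth_mm / (r_outer - r_inner),
         apex_px = c(row = apex_row, col = apex_col),
         image_size = dim(image),
         edge_residual_px = stats::sd(resid)),
    class = "image_calibration"
  )
}

#' @export
print.image_calibration <- function(x, ...) {
  cat(sprintf(
    "<image_calibration> %.4g mm/px, apex at (row %.1f, col %.1f), residual %.2f px\n",
    x$pixel_size_mm, x$apex_px["row"], x$apex_px["col"], x$edge_residual_px
  ))
  invisible(x)
}

#' Write or read an image calibration as a key-value file
#'
#' @param cal An `image_calibration`.
#' @param path File path (YAML).
#' @export
write_calibration <- function(cal, path) {
  yaml::write_yaml(list(
    pixel_size_mm = cal$pixel_size_mm,
    apex_row = unname(cal$apex_px["row"]),
    apex_col = unname(cal$apex_px["col"]),
    image_rows = cal$image_size[1], image_cols = cal$image_size[2],
    edge_residual_px = cal$edge_residual_px
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  v <- yaml::read_yaml(path)
  structure(
    list(pixel_size_mm = v$pixel_size_mm,
         apex_px = c(row = v$apex_row, col = v$apex_col),
         image_size = c(v$image_rows, v$image_cols),
         edge_residual_px = v$edge_residual_px),
    class = "image_calibration"
  )
}

#' Map a Cartesian estimate to image pixels
#'
#' `col = apex_col + x / pixel_size`, `row = apex_row + y / pixel_size`;
#' axis-aligned uncertainties are divided by the pixel size.
#'
#' @param est A `cartesian_estimate`.
#' @param cal An `image_calibration`.
#' @return One-row tibble with `row`, `col`, `sigma_row`, `sigma_col`
#'   (pixels) and `valid`.
#' @export
to_pixel <- function(est, cal) {
  stopifnot(inherits(est, "cartesian_estimate"),
            inherits(cal, "image_calibration"))
  tibble::tibble(
    row = unname(cal$apex_px["row"]) + est$y_mm / cal$pixel_size_mm,
    col = unname(cal$apex_px["col"]) + est$x_mm / cal$pixel_size_mm,
    sigma_row = est$sigma_y_mm / cal$pixel_size_mm,
    sigma_col = est$sigma_x_mm / cal$pixel_size_mm,
    valid = est$valid
  )
}

#' Render a synthetic B-mode fan raster
#'
#' Paints the fan sector of a probe onto a grey-scale raster: pixels whose
#' distance from the apex lies between the probe radius and radius plus
#' imaging depth, within the angular field of view, get `intensity`. Used
#' as a calibration fixture and as a playback background.
#'
#' @param geometry A [probe_geometry()].
#' @param pixel_size_mm Pixel size (mm per pixel).
#' @param apex_px Apex position `c(row, col)` in pixels (may be outside the
#'   image, e.g. a negative row).
#' @param image_size `c(rows, cols)`.
#' @param intensity Fan grey level in `[0, 1]`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
render_fan_image <- function(geometry, pixel_size_mm, apex_px, image_size,
                             intensity = 0.8) {
  rows <- matrix(seq_len(image_size[1]), image_size[1], image_size[2])
  cols <- matrix(seq_len(image_size[2]), image_size[1], image_size[2],
                 byrow = TRUE)
  dy <- (rows - apex_px[1]) * pixel_size_mm
  dx <- (cols - apex_px[2]) * pixel_size_mm
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy) * 180 / pi
  inside <- r >= geometry$rho_mm &
    r <= geometry$rho_mm + geometry$imaging_depth_mm &
    abs(ang) <= geometry$fov_deg / 2 & dy > 0
  img <- matrix(0, image_size[1], image_size[2])
  img[inside] <- intensity
  img
}

#' Draw a tracking cross-hair on an image
#'
#' Overlays a cross-hair at a pixel position, with arm lengths optionally
#' scaled by the axis-aligned pixel uncertainties so the cursor grows as
#' tracking confidence falls.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param px One-row tibble from [to_pixel()].
#' @param size Base arm half-length (pixels).
#' @param scale_by_sigma If `TRUE`, arm half-lengths are
#'   `size + 2 * sigma` per axis.
#' @param value Grey level of the cursor.
#' @return The image with the cross-hair burnt in.
#' @export
draw_crosshair <- function(image, px, size = 8, scale_by_sigma = TRUE,
                           value = 1) {
  if (!isTRUE(px$valid)) return(image)
  r0 <- round(px$row)
  c0 <- round(px$col)
  len_r <- round(size + if (scale_by_sigma) 2 * px$sigma_row else 0)
  len_c <- round(size + if (scale_by_sigma) 2 * px$sigma_col else 0)
  rr <- max(1, r0 - len_r):min(nrow(image), r0 + len_r)
  cc <- max(1, c0 - len_c):min(ncol(image), c0 + len_c)
  if (r0 >= 1 && r0 <= nrow(image)) image[r0, cc] <- value
  if (c0 >= 1 && c0 <= ncol(image)) image[rr, c0] <- value
  image
}
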