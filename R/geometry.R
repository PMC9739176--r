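#' Curvilinear probe geometry
#'
#' Bundles the parameters of a convex (curvilinear) imaging probe that every
#' other step of the pipeline shares: the radius of curvature `rho_mm` of the
#' probe face, the angular field of view, the number of scan lines in one
#' B-mode frame, the sound speed assumed by the imaging system, and the
#' configured imaging depth. Scan lines fan out from the centre of curvature,
#' so tip positions are natively polar: `r` is the distance from the centre of
#' curvature and `theta` the (signed) angle from the vertical axial axis.
#' The probe face sits at `r = rho_mm`; a pulse arriving a time `t` after
#' transmission corresponds to `r = c * t + rho`.
#'
#' @param rho_mm Radius of curvature of the probe face (mm).
#' @param fov_deg Angular field of view (degrees), spanned symmetrically
#'   about the vertical axis.
#' @param n_lines Number of scan lines per frame (>= 2).
#' @param sound_speed_mps Sound speed assumed by the imaging system (m/s).
#' @param imaging_depth_mm Configured imaging depth below the probe face (mm).
#'
#' @return An object of class `probe_geometry`.
#' @examples
#' geom <- probe_geometry()
#' scan_line_angles(geom)[1:3]
#' @export
probe_geometry <- function(rho_mm = 68,
                           fov_deg = 55,
                           n_lines = 128,
                           sound_speed_mps = 1540,
                           imaging_depth_mm = 300) {
  stopifnot(
    "rho_mm must be > 0" = is.numeric(rho_mm) && length(rho_mm) == 1 && rho_mm > 0,
    "fov_deg must be in (0, 180)" = is.numeric(fov_deg) && fov_deg > 0 && fov_deg < 180,
    "sound_speed_mps must be > 0" = is.numeric(sound_speed_mps) && sound_speed_mps > 0,
    "imaging_depth_mm must be > 0" = is.numeric(imaging_depth_mm) && imaging_depth_mm > 0
  )
  if (!is.numeric(n_lines) || length(n_lines) != 1 || n_lines < 2 ||
      n_lines != round(n_lines)) {
    stop("invalid geometry: n_lines must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(
      rho_mm = as.numeric(rho_mm),
      fov_deg = as.numeric(fov_deg),
      n_lines = as.integer(n_lines),
      sound_speed_mps = as.numeric(sound_speed_mps),
      imaging_depth_mm = as.numeric(imaging_depth_mm)
    ),
    class = "probe_geometry"
  )
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("<probe_geometry>\n")
  cat(sprintf("  radius of curvature: %g mm\n", x$rho_mm))
  cat(sprintf("  field of view:       %g deg (%d scan lines)\n",
              x$fov_deg, x$n_lines))
  cat(sprintf("  imaging depth:       %g mm\n", x$imaging_depth_mm))
  cat(sprintf("  sound speed:         %g m/s\n", x$sound_speed_mps))
  invisible(x)
}

#' Scan-line angles of a probe
#'
#' Angles of the `n_lines` scan lines, evenly spaced and symmetric about the
#' vertical axis, spanning the full field of view inclusive of both edges.
#'
#' @param geometry A [probe_geometry()].
#' @return Numeric vector of `n_lines` strictly increasing angles (degrees),
#'   from `-fov_deg / 2` to `+fov_deg / 2`.
#' @export
scan_line_angles <- function(geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  seq(-geometry$fov_deg / 2, geometry$fov_deg / 2,
      length.out = geometry$n_lines)
}

#' Polar to Cartesian conversion for the probe fan
#'
#' Converts polar tip coordinates (origin at the centre of curvature, angle
#' measured from the vertical axial axis, positive towards positive lateral
#' `x`) to Cartesian coordinates. `y` is the axial coordinate, positive
#' pointing away from the probe face into the medium, so `x = r sin(theta)`
#' and `y = r cos(theta)`; depth, range and image row all increase together.
#'
#' @param r Radial distance(s) from the centre of curvature (mm), `>= 0`.
#' @param theta_deg Angle(s) from the vertical axis (degrees).
#' @return A tibble with columns `x` and `y` (mm).
#' @examples
#' polar_to_cartesian(100, 0)   # on-axis: x = 0, y = 100
#' polar_to_cartesian(100, 90)  # horizontal: x = 100, y = 0
#' @export
polar_to_cartesian <- function(r, theta_deg) {
  stopifnot("r must be >= 0" = all(r >= 0))
  th <- theta_deg * pi / 180
  tibble::tibble(x = r * sin(th), y = r * cos(th))
}

#' Cartesian to polar conversion for the probe fan
#'
#' Inverse of [polar_to_cartesian()]: `r = sqrt(x^2 + y^2)` and
#' `theta = sign(x) * acos(y / r)`, so the angle is signed with positive
#' angles on the positive-lateral side.
#'
#' @param x Lateral coordinate(s) (mm).
#' @param y Axial coordinate(s) (mm), positive into the medium.
#' @return A tibble with columns `r` (mm) and `theta_deg` (degrees).
#' @export
cartesian_to_polar <- function(x, y) {
  r <- sqrt(x^2 + y^2)
  if (any(r == 0)) {
    stop("undefined angle: (x, y) = (0, 0) has no polar angle", call. = FALSE)
  }
  theta <- sign(x) * acos(pmin(pmax(y / r, -1), 1)) * 180 / pi
  tibble::tibble(r = r, theta_deg = theta)
}

#' Read or write a probe/imaging configuration file
#'
#' Plain YAML key-value files holding the probe geometry together with the
#' acquisition parameters the tracker needs (`sample_rate_hz`,
#' `focal_depth_mm`, `trigger_to_transmit_delay_s`).
#'
#' @param path File path.
#' @return `read_probe_config()` returns a list with elements `geometry`
#'   (a [probe_geometry()]) and the remaining scalar settings.
#' @export
read_probe_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("rho_mm", "fov_deg", "n_lines", "sound_speed_mps",
                "imaging_depth_mm")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("config error: missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  geom <- probe_geometry(
    rho_mm = cfg$rho_mm, fov_deg = cfg$fov_deg, n_lines = cfg$n_lines,
    sound_speed_mps = cfg$sound_speed_mps,
    imaging_depth_mm = cfg$imaging_depth_mm
  )
  extras <- cfg[setdiff(names(cfg), required)]
  c(list(geometry = geom), extras)
}

#' @rdname read_probe_config
#' @param geometry A [probe_geometry()].
#' @param ... Further scalar settings stored alongside the geometry, e.g.
#'   `sample_rate_hz = 10e6`.
#' @export
write_probe_config <- function(geometry, path, ...) {
  stopifnot(inherits(geometry, "probe_geometry"))
  cfg <- c(unclass(geometry), list(...))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
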