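# Angle conventions shared across the package.
#
# Images follow the microscopy convention: row 1 is the top of the image and
# the anterior of the embryo; the anterior-posterior (AP) axis is vertical.
# Directed angles are measured from the anterior direction, positive
# counterclockwise in the anterior-up view, and live in (-180, 180].
# Axis (undirected) angles live in (-90, 90]; 0 = AP-aligned, +/-90 = DV.

#' Wrap a directed angle to (-180, 180] degrees
#'
#' @param theta numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(theta) {
  out <- (theta + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

#' Wrap an angle to the axis range (-90, 90] degrees
#'
#' Undirected axes are periodic with period 180 degrees; this maps any angle
#' to its axis representative in (-90, 90].
#'
#' @param theta numeric vector of angles in degrees.
#' @return axis angles in (-90, 90].
#' @export
wrap_axis_angle <- function(theta) {
  out <- (theta + 90) %% 180 - 90
  out[out == -90] <- 90
  out
}

#' Fold a signed division angle onto [0, 90]
#'
#' Division angles are reported on a folded scale where 0 means alignment with
#' the AP axis and 90 alignment with the DV axis, irrespective of the tilt
#' direction.
#'
#' @param signed_angle numeric vector of signed axis angles in (-90, 90].
#' @return folded angles in [0, 90].
#' @export
fold_angle <- function(signed_angle) {
  if (any(!is.finite(signed_angle)) ||
      any(signed_angle <= -90 - 1e-9) || any(signed_angle > 90 + 1e-9)) {
    stop("signed_angle must be finite and in (-90, 90]", call. = FALSE)
  }
  abs(signed_angle)
}

# Directed angle of the displacement (d_col, d_row) relative to the AP
# (anterior, i.e. "up") direction, positive counterclockwise in the
# anterior-up view. d_row increases downward (array convention).
angle_from_ap <- function(d_col, d_row) {
  wrap_angle(atan2(-d_col, -d_row) * 180 / pi)
}

# Unit displacement (d_col, d_row) in array coordinates for a directed angle
# measured from the AP direction. Inverse of angle_from_ap.
ap_unit_vector <- function(theta_deg) {
  t <- theta_deg * pi / 180
  cbind(d_col = -sin(t), d_row = -cos(t))
}

# Shorter-path angular difference b - a on the axis circle (period 180),
# result in [-90, 90); exactly antipodal axes resolve to +90 (counter-
# clockwise tie-break).
axis_angle_difference <- function(a, b) {
  d <- (b - a + 90) %% 180 - 90
  d[d == -90] <- 90
  d
}
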