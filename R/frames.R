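#' Wrap angles into (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length with every angle reduced modulo
#'   2*pi into the interval (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi))
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Convert world coordinates to the camera frame of a rat pose
#'
#' The world frame is right-handed with x pointing east, y north and z up
#' (units cm). The camera (eye) frame follows the computer-vision habit of
#' z pointing along the direction of travel, with y up and x to the left of
#' travel, so that the frame stays right-handed. Azimuth is measured as
#' `atan2(X, Z)` in this frame and is therefore positive for features to the
#' left of the travel direction; elevation is positive upward and negative
#' for features on the ground, given an eye height above the ground plane.
#'
#' @param points Data frame or tibble with world coordinates `x`, `y`, `z`
#'   in cm.
#' @param x,y Rat position in the ground plane (cm).
#' @param phi Heading in radians, measured counter-clockwise from the world
#'   x axis.
#' @param eye_height Height of the eye above the ground plane (cm).
#' @return Tibble with camera-frame coordinates `X` (left), `Y` (up), `Z`
#'   (forward), one row per input point.
#' @seealso [camera_to_world()]
#' @export
world_to_camera <- function(points, x, y, phi, eye_height = 2.5) {
  dx <- points$x - x
  dy <- points$y - y
  dz <- points$z - eye_height
  tibble::tibble(
    X = -sin(phi) * dx + cos(phi) * dy,
    Y = dz,
    Z = cos(phi) * dx + sin(phi) * dy
  )
}

#' Convert camera-frame coordinates back to the world frame
#'
#' Inverse of [world_to_camera()]; the two compose to the identity up to
#' numerical precision.
#'
#' @param points Data frame with camera coordinates `X`, `Y`, `Z` (cm).
#' @inheritParams world_to_camera
#' @return Tibble with world coordinates `x`, `y`, `z`.
#' @export
camera_to_world <- function(points, x, y, phi, eye_height = 2.5) {
  tibble::tibble(
    x = x + cos(phi) * points$Z - sin(phi) * points$X,
    y = y + sin(phi) * points$Z + cos(phi) * points$X,
    z = eye_height + points$Y
  )
}
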