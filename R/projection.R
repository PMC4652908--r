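#' Project 3D points to spherical camera angles
#'
#' Maps 3D point locations to azimuth/elevation pairs on the unit viewing
#' sphere: `azimuth = atan2(X, Z)` and `elevation = atan2(Y, sqrt(X^2 + Z^2))`
#' in the camera frame (z forward, y up, x left; see [world_to_camera()]).
#' Both angles are invariant to the distance of the point, so the sphere
#' radius (nominally 1 cm) never enters any computation. Elevation is
#' positive upward; with the eye above the ground plane, ground features
#' project to negative elevations.
#'
#' @param points Data frame of points. If `x`/`y`/`phi` are supplied the
#'   points are world coordinates (columns `x`, `y`, `z`) converted via
#'   [world_to_camera()]; otherwise they must already be camera coordinates
#'   (columns `X`, `Y`, `Z`).
#' @param x,y,phi Optional rat pose used to convert world points.
#' @param eye_height Eye height above ground (cm).
#' @return Tibble with columns `azimuth`, `elevation` (radians) and
#'   `distance` (cm, straight-line eye-to-point).
#' @examples
#' project_features(data.frame(X = 0, Y = 0, Z = 100))       # on-axis
#' project_features(data.frame(X = 100, Y = 0, Z = 0))       # 90 deg left
#' project_features(data.frame(X = 0, Y = -2.5, Z = 2.5))    # 45 deg down
#' @export
project_features <- function(points, x = NULL, y = NULL, phi = NULL,
                             eye_height = 2.5) {
  if (!is.null(x)) {
    points <- world_to_camera(points, x, y, phi, eye_height)
  }
  stopifnot(all(c("X", "Y", "Z") %in% names(points)))
  D <- sqrt(points$X^2 + points$Y^2 + points$Z^2)
  if (any(D < 1e-9)) {
    stop("point coincides with the camera origin; viewing direction undefined",
         call. = FALSE)
  }
  tibble::tibble(
    azimuth = atan2(points$X, points$Z),
    elevation = atan2(points$Y, sqrt(points$X^2 + points$Z^2)),
    distance = D
  )
}

#' Distance to a plane along a viewing direction
#'
#' For a feature seen at `(azimuth, elevation)` lying on the plane
#' `n . P = d` (camera frame), the eye-to-feature distance is
#' `D = d / (n_x sin(az) cos(el) + n_y sin(el) + n_z cos(az) cos(el))`.
#' The default plane is the ground underneath the eye, `Y = -offset` with
#' normal `(0, -1, 0)`, for which `D = -offset / sin(elevation)`. `D` scales
#' linearly in `offset` at fixed angles. Directions grazing the plane
#' (denominator near zero, e.g. the horizon for the ground plane) are
#' degenerate and yield `Inf` with a warning.
#'
#' @param azimuth,elevation Viewing angles (radians), recycled to a common
#'   length.
#' @param offset Plane offset `d` along its normal (cm); for the ground
#'   plane, the eye height.
#' @param normal Unit plane normal in camera coordinates `(n_x, n_y, n_z)`.
#' @return Numeric vector of distances (cm); `Inf` where degenerate.
#' @examples
#' ground_distance(0, -pi / 4, offset = 2.5)  # 2.5 * sqrt(2)
#' @export
ground_distance <- function(azimuth, elevation, offset = 2.5,
                            normal = c(0, -1, 0)) {
  stopifnot(length(normal) == 3, offset > 0)
  den <- normal[1] * sin(azimuth) * cos(elevation) +
    normal[2] * sin(elevation) +
    normal[3] * cos(azimuth) * cos(elevation)
  bad <- abs(den) < 1e-9
  if (any(bad)) {
    warning("grazing viewing direction(s): distance to plane is unbounded",
            call. = FALSE)
  }
  out <- offset / den
  out[bad] <- Inf
  out
}

#' Analytic optic flow of ground-plane features under curvilinear motion
#'
#' Angular velocities of ground features for a rat translating with forward
#' speed `v_z` and yawing at `omega_y` above a ground plane at eye height
#' `d`:
#' \deqn{\dot\theta = -\frac{\sin\phi}{d\cos\phi}\sin\theta\, v_z - \omega_y,
#'  \qquad
#'  \dot\phi = -\frac{\sin\phi}{d\cos\phi}\cos\theta\sin\phi\cos\phi\, v_z,}
#' with \eqn{\theta} azimuth and \eqn{\phi} elevation (negative for ground
#' features, so the translational prefactor is positive). The signs here are
#' fixed against a central finite-difference oracle on the projected angles,
#' not taken on faith from any printed template: a feature passed on the
#' left drifts further left (\eqn{\dot\theta > 0}) and a feature ahead dips
#' downward (\eqn{\dot\phi < 0}) as it is approached. Features at
#' `elevation == 0` sit at infinite ground distance and are degenerate.
#'
#' @param obs Data frame with columns `azimuth` and `elevation` (radians) of
#'   ground features.
#' @param v_z Forward speed (cm/s).
#' @param omega_y Yaw rate (rad/s), positive counter-clockwise.
#' @param d Eye height above the ground plane (cm).
#' @return `obs` with columns `azimuth_rate` and `elevation_rate` (rad/s)
#'   appended.
#' @export
flow_ground <- function(obs, v_z, omega_y, d = 2.5) {
  stopifnot(all(c("azimuth", "elevation") %in% names(obs)), d > 0)
  if (any(abs(obs$elevation) < 1e-9)) {
    stop("feature at the horizon (elevation 0): infinite ground distance",
         call. = FALSE)
  }
  sphi <- sin(obs$elevation)
  cphi <- cos(obs$elevation)
  pref <- -sphi / (d * cphi)
  dplyr::mutate(
    tibble::as_tibble(obs),
    azimuth_rate = pref * sin(.data$azimuth) * v_z - omega_y,
    elevation_rate = pref * cos(.data$azimuth) * sphi * cphi * v_z
  )
}

#' Analytic optic flow for general six-component self-motion
#'
#' Instantaneous angular velocities of static 3D points for a camera moving
#' with linear velocity `v = (v_x, v_y, v_z)` and rotating at
#' `omega = (omega_x, omega_y, omega_z)` (camera frame). Points move as
#' `dP/dt = -v - omega x P`; the angle rates follow from differentiating the
#' spherical projection. Restricting to `v = (0, 0, v_z)`,
#' `omega = (0, omega_y, 0)` and ground-plane points reproduces
#' [flow_ground()] exactly, which is checked in the test-suite.
#'
#' @param obs Data frame with columns `azimuth`, `elevation` (radians) and
#'   `distance` (cm), as from [project_features()].
#' @param v Length-3 linear velocity (cm/s), camera frame.
#' @param omega Length-3 angular velocity (rad/s), camera frame.
#' @return `obs` with `azimuth_rate` and `elevation_rate` (rad/s) appended.
#' @export
flow_general <- function(obs, v, omega) {
  stopifnot(all(c("azimuth", "elevation", "distance") %in% names(obs)),
            length(v) == 3, length(omega) == 3)
  th <- obs$azimuth
  el <- obs$elevation
  D <- obs$distance
  X <- D * sin(th) * cos(el)
  Y <- D * sin(el)
  Z <- D * cos(th) * cos(el)
  dX <- -v[1] - (omega[2] * Z - omega[3] * Y)
  dY <- -v[2] - (omega[3] * X - omega[1] * Z)
  dZ <- -v[3] - (omega[1] * Y - omega[2] * X)
  rho2 <- X^2 + Z^2
  rho <- sqrt(rho2)
  drho <- (X * dX + Z * dZ) / rho
  dplyr::mutate(
    tibble::as_tibble(obs),
    azimuth_rate = (dX * Z - dZ * X) / rho2,
    elevation_rate = (dY * rho - Y * drho) / (rho2 + Y^2)
  )
}

# ---- internal batched observation machinery -------------------------------

# Per-step ground-feature observations for a whole trajectory, as matrices
# (n_steps x n_features). Step j runs from pose row j to row j + 1: angles are
# evaluated at position row j with the post-turn heading of row j + 1, and the
# rates use the speed/yaw executed during that step, so that analytic flow,
# velocity estimation and path integration share one discretization and the
# noise-free pipeline is exact to machine precision.
ground_flow_matrices <- function(traj, env, config = "A", v_fov = 120) {
  box <- env_config(env, config)
  d <- box$eye_height
  f <- env_features(env, config)
  f <- f[f$surface == "ground", ]
  n <- nrow(traj)
  m <- nrow(f)
  px <- traj$x[-n]
  py <- traj$y[-n]
  ph <- traj$phi[-1]
  v <- traj$v[-1]
  w <- traj$omega[-1] * pi / 180

  dx <- outer(px, f$x, function(a, b) b - a)
  dy <- outer(py, f$y, function(a, b) b - a)
  rho <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  theta <- wrap_angle(bearing - ph)
  elev <- atan2(-d, rho)
  mask <- abs(elev) <= (v_fov / 2) * pi / 180

  sphi <- sin(elev)
  cphi <- cos(elev)
  pref <- -sphi / (d * cphi)
  theta_dot <- pref * sin(theta) * v - w
  phi_dot <- pref * cos(theta) * sphi * cphi * v

  list(theta = theta, phi = elev, theta_dot = theta_dot, phi_dot = phi_dot,
       mask = mask, d = d, v_true = v, omega_true = w)
}

# Per-sample wall-feature observations: allocentric bearings, camera angles
# and visibility masks, one matrix column per wall feature (n x m). Observed
# geometry uses the active configuration; the memorized positions fed to the
# triangulation are always the configuration-A coordinates.
wall_angle_matrices <- function(traj, env, config = "A", v_fov = 120) {
  box <- env_config(env, config)
  d <- box$eye_height
  f <- env_features(env, config)
  f <- f[f$surface %in% c("N-wall", "S-wall", "W-wall", "E-wall"), ]
  mem <- env_features(env, "A")
  mem <- mem[match(f$id, mem$id), ]

  dx <- outer(traj$x, f$x, function(a, b) b - a)
  dy <- outer(traj$y, f$y, function(a, b) b - a)
  rho <- sqrt(dx^2 + dy^2)
  dz <- matrix(f$z - d, nrow(traj), nrow(f), byrow = TRUE)
  elev <- atan2(dz, rho)
  bearing <- atan2(dy, dx)
  mask <- abs(elev) <= (v_fov / 2) * pi / 180

  list(bearing = bearing, elevation = elev,
       azimuth = wrap_angle(bearing - traj$phi),
       mask = mask,
       surface = f$surface, feature_id = f$id,
       mem_x = mem$x, mem_y = mem$y)
}
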