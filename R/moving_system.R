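#' Least-squares self-motion estimate from ground-plane optic flow
#'
#' Recovers the forward speed `v_z` and yaw rate `omega_y` that best explain
#' the sensed angular velocities of ground features, by minimizing the sum of
#' squared deviations between the sensed rates and the analytic ground-flow
#' model (see [flow_ground()]):
#' \deqn{F(v_z, \omega_y) = \sum_i \big(\hat{\dot\theta}_i - g_i v_z +
#'   \omega_y\big)^2 + \big(\hat{\dot\phi}_i - h_i v_z\big)^2,}
#' with \eqn{g_i = -\sin\theta_i \sin\phi_i / (d\cos\phi_i)} and
#' \eqn{h_i = -\cos\theta_i \sin^2\phi_i / d}. The minimizer solves a 2x2
#' normal-equation system in closed form; on self-consistent (noise-free)
#' flow the recovery is exact to machine precision.
#'
#' @param obs Data frame of ground-feature observations with columns
#'   `azimuth`, `elevation` (radians) and sensed rates `azimuth_rate`,
#'   `elevation_rate` (rad/s).
#' @param d Eye height above the ground plane (cm).
#' @return A one-row tibble with `v_z_hat` (cm/s), `omega_y_hat` (rad/s),
#'   `n_ground` (features used) and `condition` (normal-equation
#'   denominator; near-zero values flag degenerate geometry).
#' @examples
#' obs <- project_features(data.frame(x = c(10, 40, 60, 80), y = c(20, 70, 10, 50),
#'                                    z = 0), x = 50, y = 40, phi = 0.3)
#' obs <- flow_ground(obs, v_z = 13, omega_y = 0.5)
#' estimate_velocity(obs)  # recovers (13, 0.5) exactly
#' @export
estimate_velocity <- function(obs, d = 2.5) {
  stopifnot(all(c("azimuth", "elevation", "azimuth_rate", "elevation_rate")
                %in% names(obs)))
  n <- nrow(obs)
  if (n < 2) {
    stop("need at least 2 ground features to estimate self-motion",
         call. = FALSE)
  }
  sphi <- sin(obs$elevation)
  cphi <- cos(obs$elevation)
  g <- -sin(obs$azimuth) * sphi / (d * cphi)
  h <- -cos(obs$azimuth) * sphi^2 / d
  Sgg <- sum(g^2 + h^2)
  Sg <- sum(g)
  Sgt <- sum(g * obs$azimuth_rate + h * obs$elevation_rate)
  St <- sum(obs$azimuth_rate)
  den <- Sgg - Sg^2 / n
  if (!is.finite(den) || abs(den) < 1e-12) {
    stop("degenerate flow geometry (all features near the horizon?): ",
         "normal equations are singular", call. = FALSE)
  }
  v_hat <- (Sgt - Sg * St / n) / den
  tibble::tibble(
    v_z_hat = v_hat,
    omega_y_hat = (v_hat * Sg - St) / n,
    n_ground = n,
    condition = den
  )
}

#' Path-integrate velocity estimates into a location estimate
#'
#' Accumulates per-step speed and yaw estimates into heading and position:
#' the heading is the running sum of the yaw estimates
#' (`phi_j = phi0 + dt * sum(omega_1..j)`) and the position the running sum
#' of the displacement `dt * v_j` along the updated heading -- the same
#' heading-first discretization used by [synthesize_trajectory()], so that
#' exact velocity estimates reproduce the trajectory exactly.
#'
#' @param v_hat Per-step forward-speed estimates (cm/s).
#' @param omega_hat Per-step yaw-rate estimates (rad/s); same length as
#'   `v_hat`.
#' @param x0,y0 Initial location (cm).
#' @param phi0 Initial heading (radians).
#' @param dt Time step (s).
#' @return Tibble with `length(v_hat) + 1` rows (the initial pose first) and
#'   columns `t`, `x_hat`, `y_hat`, `phi_hat`.
#' @examples
#' integrate_path(rep(10, 20), rep(0, 20), dt = 0.05)  # 10 cm along +x
#' @export
integrate_path <- function(v_hat, omega_hat, x0 = 0, y0 = 0, phi0 = 0,
                           dt = 0.05) {
  if (length(v_hat) != length(omega_hat)) {
    stop("v_hat and omega_hat must have the same length", call. = FALSE)
  }
  phi <- phi0 + cumsum(omega_hat * dt)
  tibble::tibble(
    t = (0:length(v_hat)) * dt,
    x_hat = x0 + c(0, cumsum(v_hat * dt * cos(phi))),
    y_hat = y0 + c(0, cumsum(v_hat * dt * sin(phi))),
    phi_hat = c(phi0, phi)
  )
}

#' Location estimate of the moving feature system along a trajectory
#'
#' Runs the full optic-flow pipeline for every step of a trajectory:
#' generate the analytic angular velocities of the visible ground features,
#' optionally superimpose Gaussian noise in the angular-velocity domain
#' (see [noise_spec()]), estimate `(v_z, omega_y)` by [estimate_velocity()]'s
#' closed form, and path-integrate with [integrate_path()]. Only ground
#' features enter this system. Because position is accumulated, errors in
#' the velocity estimates are integrated over time -- the defining contrast
#' with [estimate_path_static()]. Wall position never enters, so the
#' estimate tracks the true (compressed-range) positions unchanged when
#' barriers move.
#'
#' @param traj A [synthesize_trajectory()] result.
#' @param env The [build_environment()] the trajectory lives in.
#' @param config "A" or "B": box configuration the rat is observing.
#' @param noise `NULL` (noise-free) or a [noise_spec()] with domain
#'   `"angular_velocity"`.
#' @param seed Seed for the noise draws (ignored when `noise` is `NULL`).
#' @return Tibble of class `ts_location_estimate`, aligned row-for-row with
#'   `traj`: columns `t`, `x_hat`, `y_hat`, `phi_hat`, `v_hat` (cm/s),
#'   `omega_hat` (deg/s) and `source = "moving"`.
#' @export
estimate_path_moving <- function(traj, env, config = c("A", "B"),
                                 noise = NULL, seed = NULL) {
  stopifnot(inherits(env, "box_environment"))
  config <- match.arg(config)
  box <- env_config(env, config)
  gf <- ground_flow_matrices(traj, env, config)
  td <- gf$theta_dot
  pd <- gf$phi_dot
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (noise$domain != "angular_velocity") {
      stop("moving-system noise must live in the angular_velocity domain",
           call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    mu <- noise$mean * pi / 180
    sg <- noise$sd * pi / 180
    td <- td + matrix(stats::rnorm(length(td), mu, sg), nrow(td))
    pd <- pd + matrix(stats::rnorm(length(pd), mu, sg), nrow(pd))
  }
  est <- estimate_velocity_batch(gf$theta, gf$phi, td, pd, gf$mask, box$eye_height)
  dt <- 1 / attr(traj, "f_sample")
  path <- integrate_path(est$v, est$omega, x0 = traj$x[1], y0 = traj$y[1],
                         phi0 = traj$phi[1], dt = dt)
  out <- dplyr::mutate(
    path,
    t = traj$t,
    v_hat = c(0, est$v),
    omega_hat = c(0, est$omega) * 180 / pi,
    source = "moving"
  )
  class(out) <- c("ts_location_estimate", class(out))
  out
}

# Vectorized closed-form least squares over all steps at once. theta/phi and
# the (possibly noisy) rate matrices are n_steps x n_features; masked-out
# features are dropped from the per-step sums.
estimate_velocity_batch <- function(theta, phi, theta_dot, phi_dot, mask, d) {
  w <- mask * 1
  sphi <- sin(phi)
  cphi <- cos(phi)
  g <- -sin(theta) * sphi / (d * cphi)
  h <- -cos(theta) * sphi^2 / d
  n <- rowSums(w)
  Sgg <- rowSums(w * (g^2 + h^2))
  Sg <- rowSums(w * g)
  Sgt <- rowSums(w * (g * theta_dot + h * phi_dot))
  St <- rowSums(w * theta_dot)
  den <- Sgg - Sg^2 / n
  bad <- !is.finite(den) | abs(den) < 1e-12 | n < 2
  if (any(bad)) {
    stop(sum(bad), " step(s) with degenerate ground-flow geometry; ",
         "cannot estimate self-motion", call. = FALSE)
  }
  v <- (Sgt - Sg * St / n) / den
  list(v = v, omega = (v * Sg - St) / n)
}
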