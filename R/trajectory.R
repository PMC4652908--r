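#' Movement statistics for synthetic foraging trajectories
#'
#' Parameters of the stochastic movement model: forward running speeds are
#' drawn from a Rayleigh distribution whose peak (mode) sits at `rayleigh_peak`
#' and yaw rates from a normal distribution, independently at every sample.
#' Within `collision_distance` of a barrier the rat performs a two-step
#' avoidance maneuver (slow down toward `min_speed`, turn away from the wall).
#'
#' @param rayleigh_peak Peak location of the Rayleigh speed distribution
#'   (cm/s).
#' @param yaw_mean Mean of the yaw-rate distribution (deg/s).
#' @param yaw_sd Standard deviation of the yaw-rate distribution (deg/s).
#' @param f_sample Sampling rate (Hz).
#' @param n_sample Number of samples in a trajectory.
#' @param min_speed Minimal running speed the avoidance maneuver decays
#'   toward (cm/s).
#' @param collision_distance Distance to a barrier at which avoidance
#'   engages (cm).
#' @return An object of class `movement_params` (a list).
#' @export
movement_params <- function(rayleigh_peak = 13.25,
                            yaw_mean = 0,
                            yaw_sd = 337.93,
                            f_sample = 20,
                            n_sample = 50000,
                            min_speed = 5,
                            collision_distance = 15) {
  stopifnot(rayleigh_peak > 0, yaw_sd > 0, f_sample > 0,
            n_sample >= 2, min_speed >= 0, collision_distance > 0)
  structure(
    list(rayleigh_peak = rayleigh_peak, yaw_mean = yaw_mean, yaw_sd = yaw_sd,
         f_sample = f_sample, n_sample = n_sample, min_speed = min_speed,
         collision_distance = collision_distance),
    class = "movement_params"
  )
}

#' @export
print.movement_params <- function(x, ...) {
  cat(sprintf(
    "<movement_params: Rayleigh peak %g cm/s, yaw N(%g, %g) deg/s, %d samples @ %g Hz>\n",
    x$rayleigh_peak, x$yaw_mean, x$yaw_sd, x$n_sample, x$f_sample))
  invisible(x)
}

# Outward unit normals of the four walls, indexed S, N, W, E.
wall_normals <- function() {
  matrix(c(0, -1, 0, 1, -1, 0, 1, 0), ncol = 2, byrow = TRUE,
         dimnames = list(c("S", "N", "W", "E"), c("nx", "ny")))
}

#' Synthesize a foraging trajectory inside the box
#'
#' Draws independent speed and yaw-rate samples at every time step
#' (Rayleigh and normal, see [movement_params()]) and integrates them into a
#' pose sequence: the heading is updated first, then the position steps along
#' the new heading. When the rat is within `collision_distance` of a wall and
#' heading within 90 degrees of that wall's outward normal, a two-step
#' avoidance maneuver replaces the drawn values: the speed is reduced by half
#' the difference to `min_speed`, and the heading is rotated to the inward
#' wall normal plus a random extra rotation (uniform on 0-90 degrees,
#' continuing in the same turning direction) so that corner encounters do not
#' settle into periodic cycles. If an extreme step would still leave the box,
#' the position is clamped 0.1 cm inside the wall; the number of clamps is
#' recorded in the `clamped` attribute.
#'
#' @param env A [build_environment()] result.
#' @param params A [movement_params()] object.
#' @param seed Integer seed for reproducibility.
#' @param config "A" or "B": which box the rat forages in.
#' @param x0,y0 Initial location (cm); defaults to the box reference corner
#'   shifted just inside.
#' @param phi0 Initial heading (radians).
#' @return A tibble of class `ts_trajectory` with `n_sample` rows and columns
#'   `t` (s), `x`, `y` (cm), `phi` (rad, heading after the step's turn),
#'   `v` (cm/s) and `omega` (deg/s) -- the speed and yaw rate executed during
#'   the step that ends at this row's pose. Row 1 is the initial pose with
#'   `v = omega = 0`. Attributes: `config` (the active `box_config`),
#'   `f_sample`, `clamped`.
#' @examples
#' env <- build_environment(box_config("A"), seed = 1)
#' traj <- synthesize_trajectory(env, movement_params(n_sample = 2000), seed = 2)
#' range(traj$x); range(traj$y)
#' @export
synthesize_trajectory <- function(env, params = movement_params(), seed = 1,
                                  config = c("A", "B"),
                                  x0 = NULL, y0 = NULL, phi0 = 0) {
  stopifnot(inherits(env, "box_environment"), inherits(params, "movement_params"))
  config <- match.arg(config)
  box <- env_config(env, config)
  wx <- box$width_x
  ly <- box$length_y
  if (params$collision_distance >= min(wx, ly) / 2) {
    stop("collision_distance must be smaller than half the box size",
         call. = FALSE)
  }
  if (is.null(x0)) x0 <- 1
  if (is.null(y0)) y0 <- 1
  stopifnot(x0 >= 0, x0 <= wx, y0 >= 0, y0 <= ly)

  n <- params$n_sample
  dt <- 1 / params$f_sample
  if (!is.null(seed)) set.seed(seed)
  speeds <- rayleigh_draw(n - 1, params$rayleigh_peak)
  yaws <- stats::rnorm(n - 1, params$yaw_mean, params$yaw_sd) * pi / 180
  # Pre-drawn avoidance rotations; consumed one per avoidance event.
  extra <- stats::runif(n - 1, 0, pi / 2)

  nrm <- wall_normals()
  coll <- params$collision_distance
  vmin <- params$min_speed

  x <- numeric(n); y <- numeric(n); phi <- numeric(n)
  v_out <- numeric(n); w_out <- numeric(n)
  x[1] <- x0; y[1] <- y0; phi[1] <- wrap_angle(phi0)
  clamped <- 0L

  for (j in seq_len(n - 1)) {
    px <- x[j]; py <- y[j]; ph <- phi[j]
    v <- speeds[j]
    w <- yaws[j]
    hx <- cos(ph); hy <- sin(ph)

    # distances to S, N, W, E walls and facing test against outward normals
    d_wall <- c(py, ly - py, px, wx - px)
    facing <- c(-hy, hy, -hx, hx) > 0
    hit <- which(d_wall < coll & facing)
    if (length(hit) > 0) {
      wall <- hit[which.min(d_wall[hit])]
      v <- v - (v - vmin) / 2
      # turn toward the inward normal (plus the randomized overshoot),
      # executing the full rotation over about a quarter second; the
      # avoidance state persists over successive steps until the heading
      # clears the wall
      n_in <- -nrm[wall, ]
      delta <- wrap_angle(atan2(n_in[2], n_in[1]) - ph)
      delta <- delta + sign(delta) * extra[j]
      w <- delta * 4
    }

    ph_new <- wrap_angle(ph + w * dt)
    nx <- px + v * dt * cos(ph_new)
    ny <- py + v * dt * sin(ph_new)
    if (nx < 0 || nx > wx || ny < 0 || ny > ly) {
      # clamp just inside and recompute the effective speed/heading from the
      # realized displacement, so that the recorded velocities always
      # integrate exactly to the recorded poses
      nx <- min(max(nx, 0.1), wx - 0.1)
      ny <- min(max(ny, 0.1), ly - 0.1)
      clamped <- clamped + 1L
      disp <- sqrt((nx - px)^2 + (ny - py)^2)
      v <- disp / dt
      if (disp > 1e-12) {
        ph_new <- atan2(ny - py, nx - px)
        w <- wrap_angle(ph_new - ph) / dt
      } else {
        ph_new <- ph
        w <- 0
      }
    }
    x[j + 1] <- nx; y[j + 1] <- ny; phi[j + 1] <- ph_new
    v_out[j + 1] <- v; w_out[j + 1] <- w * 180 / pi
  }

  out <- tibble::tibble(
    t = (seq_len(n) - 1) * dt,
    x = x, y = y, phi = phi, v = v_out, omega = w_out
  )
  class(out) <- c("ts_trajectory", class(out))
  attr(out, "config") <- box
  attr(out, "f_sample") <- params$f_sample
  attr(out, "clamped") <- clamped
  out
}

# Rayleigh draws parameterized by the distribution's peak (= scale sigma).
rayleigh_draw <- function(n, peak) {
  peak * sqrt(-2 * log(stats::runif(n)))
}

#' Fit the movement statistics back from a trajectory
#'
#' Recovers the generative movement parameters: the maximum-likelihood
#' Rayleigh scale (= peak location) of the forward speeds,
#' `sqrt(sum(v^2) / (2 n))`, and the sample mean and standard deviation of
#' the yaw rates. The initial rest row is dropped. On long trajectories the
#' fitted values sit within a few percent of the generative ones; the
#' residual bias (slightly lower speed peak, slightly higher yaw spread) is
#' the footprint of the collision-avoidance maneuvers.
#'
#' @param traj A trajectory tibble with columns `v` (cm/s) and `omega`
#'   (deg/s), as produced by [synthesize_trajectory()].
#' @return An object of class `movement_fit` with fields `rayleigh_peak`,
#'   `yaw_mean`, `yaw_sd` and `n`; see [tidy.movement_fit()].
#' @examples
#' env <- build_environment(box_config("A"), seed = 1)
#' traj <- synthesize_trajectory(env, movement_params(n_sample = 5000), seed = 2)
#' fit_movement_statistics(traj)
#' @export
fit_movement_statistics <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("v", "omega") %in% names(traj)))
  v <- traj$v[-1]
  w <- traj$omega[-1]
  if (length(v) < 1000) {
    stop("trajectory too short to fit movement statistics (need >= 1000 samples)",
         call. = FALSE)
  }
  if (stats::sd(v) == 0 || stats::sd(w) == 0) {
    stop("degenerate trajectory: constant speed or yaw rate", call. = FALSE)
  }
  structure(
    list(rayleigh_peak = sqrt(sum(v^2) / (2 * length(v))),
         yaw_mean = mean(w),
         yaw_sd = stats::sd(w),
         n = length(v)),
    class = "movement_fit"
  )
}

#' @export
print.movement_fit <- function(x, ...) {
  cat(sprintf(
    "<movement_fit: Rayleigh peak %.2f cm/s, yaw mean %.2f, sd %.2f deg/s (n = %d)>\n",
    x$rayleigh_peak, x$yaw_mean, x$yaw_sd, x$n))
  invisible(x)
}

#' Tidy a movement-statistics fit
#'
#' @param x A `movement_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`term`, `estimate`,
#'   `unit`).
#' @export
tidy.movement_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rayleigh_peak", "yaw_mean", "yaw_sd"),
    estimate = c(x$rayleigh_peak, x$yaw_mean, x$yaw_sd),
    unit = c("cm/s", "deg/s", "deg/s")
  )
}

#' Glance at a movement-statistics fit
#'
#' @inheritParams tidy.movement_fit
#' @return A one-row tibble with the fitted parameters and sample size.
#' @export
glance.movement_fit <- function(x, ...) {
  tibble::tibble(
    rayleigh_peak = x$rayleigh_peak,
    yaw_mean = x$yaw_mean,
    yaw_sd = x$yaw_sd,
    n = x$n
  )
}
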