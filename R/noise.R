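#' Gaussian observation-noise specification
#'
#' Describes independent, identically distributed Gaussian noise added to
#' the visual observations, in one of two domains: `"angular_velocity"`
#' perturbs the sensed angular velocities of ground features (the moving
#' feature system's input; units deg/s), `"angle"` perturbs the sensed
#' angular directions of wall landmarks (the static feature system's input;
#' units deg). Fresh draws are made for every feature at every time step,
#' for both the azimuth and the elevation component. A zero mean gives
#' "bias-free" noise; a nonzero mean gives "biased" noise whose integrated
#' effect on the moving system grows quadratically.
#'
#' @param domain `"angular_velocity"` or `"angle"`.
#' @param mean Noise mean (deg/s or deg).
#' @param sd Noise standard deviation (deg/s or deg); non-negative.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec("angular_velocity", mean = 0, sd = 1.75)
#' noise_spec("angle", mean = 0.8, sd = 1)
#' @export
noise_spec <- function(domain = c("angular_velocity", "angle"),
                       mean = 0, sd = 1) {
  domain <- match.arg(domain)
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  structure(list(domain = domain, mean = mean, sd = sd),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  unit <- if (x$domain == "angular_velocity") "deg/s" else "deg"
  cat(sprintf("<noise_spec %s: N(%g, %g) %s>\n", x$domain, x$mean, x$sd, unit))
  invisible(x)
}

#' Superimpose Gaussian noise on angular observations
#'
#' Adds independent draws from `N(mean, sd)` (converted to radians) to the
#' observation columns matching the spec's domain: `azimuth_rate` and
#' `elevation_rate` for `"angular_velocity"`, `azimuth` and `elevation` for
#' `"angle"`. One fresh draw per row and component; successive draws are
#' uncorrelated.
#'
#' @param obs Data frame of observations carrying the relevant columns.
#' @param spec A [noise_spec()].
#' @param seed Optional seed for reproducible draws.
#' @return `obs` with the relevant columns perturbed.
#' @export
perturb <- function(obs, spec, seed = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  cols <- if (spec$domain == "angular_velocity") {
    c("azimuth_rate", "elevation_rate")
  } else {
    c("azimuth", "elevation")
  }
  if (!all(cols %in% names(obs))) {
    stop("observations lack the ", spec$domain, " columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(obs)
  mu <- spec$mean * pi / 180
  sg <- spec$sd * pi / 180
  for (cl in cols) {
    obs[[cl]] <- obs[[cl]] + stats::rnorm(n, mu, sg)
  }
  obs
}

#' Domain-independent signal-to-noise ratio in decibels
#'
#' `SNR = 20 * log10( sum(s^2) / sum((m - s)^2) )` for a clean signal `s`
#' and a measured (noisy) signal `m`. Taking twenty (not ten) times the
#' log of the power ratio is deliberate: it is the definition under which
#' the package's reported dB values are produced, and it makes noise
#' strengths comparable across the angle and angular-velocity domains,
#' where the raw units differ. The ratio is scale-invariant in the units of
#' `s` and `m`; scaling the signal by 10 at fixed noise adds +40 dB under
#' this definition.
#'
#' @param clean Numeric vector, the noise-free signal.
#' @param noisy Numeric vector, the measured signal including noise; same
#'   length as `clean`.
#' @return SNR in dB (scalar). Identical signals give `Inf` with a warning.
#' @examples
#' s <- sin(seq(0, 10, by = 0.01))
#' snr_db(s, s + rnorm(length(s), 0, 0.01))
#' @export
snr_db <- function(clean, noisy) {
  stopifnot(length(clean) == length(noisy))
  num <- sum(clean^2)
  den <- sum((noisy - clean)^2)
  if (den == 0) {
    warning("measured signal equals the clean signal: SNR is infinite",
            call. = FALSE)
    return(Inf)
  }
  20 * log10(num / den)
}

#' Session-level SNR of a noise specification on a trajectory
#'
#' Computes the Eq-21-style SNR over a whole trajectory for the observation
#' stream the spec's domain perturbs. In the angular-velocity domain the
#' clean signal is the azimuthal angular velocity of every visible ground
#' feature at every step (noise is drawn for the elevation rates too, but
#' only the azimuth rates define the signal); in the angle domain the clean
#' signal concatenates the azimuth and elevation angles of every visible
#' wall landmark, both perturbed.
#'
#' @param traj A [synthesize_trajectory()] result.
#' @param env The environment observed.
#' @param spec A [noise_spec()].
#' @param config "A" or "B".
#' @param seed Seed for the noise draws.
#' @return SNR in dB (scalar).
#' @export
observation_snr <- function(traj, env, spec, config = "A", seed = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  mu <- spec$mean * pi / 180
  sg <- spec$sd * pi / 180
  if (spec$domain == "angular_velocity") {
    gf <- ground_flow_matrices(traj, env, config)
    s <- gf$theta_dot[gf$mask]
    snr_db(s, s + stats::rnorm(length(s), mu, sg))
  } else {
    wa <- wall_angle_matrices(traj, env, config)
    s <- c(wa$azimuth[wa$mask], wa$elevation[wa$mask])
    snr_db(s, s + stats::rnorm(length(s), mu, sg))
  }
}

#' Brownian-motion statistics of accumulated path-integration error
#'
#' When the per-step speed and yaw estimates are integrated directly --
#' radial distance `l(t_n) = dt * sum(v_j)` and angle
#' `phi(t_n) = dt * sum(omega_j)`, without the polar-to-Cartesian transform
#' -- Gaussian per-step estimation errors make the accumulated error a
#' Brownian motion (with drift when the noise is biased): its mean squared
#' value after `n` steps is `n * sigma^2 + n^2 * mu^2`, where `mu` and
#' `sigma` are the mean and standard deviation of the per-step error
#' increments. This function measures the empirical mean squared error
#' across trials at each lag and overlays that two-term model, with `mu`
#' and `sigma` estimated from the pooled per-step increments. Bias-free
#' noise gives linear growth; biased noise adds the parabola. The
#' Cartesian-integrated position estimate does not follow this model (the
#' coordinate transform mixes the errors), which is why its Euclidean error
#' saturates instead (see [euclidean_error()]).
#'
#' @param err Numeric matrix, trials x time, of accumulated error
#'   (truth minus estimate of the integrated quantity); the first column
#'   should be the error at the first integration step.
#' @param dt Time step (s).
#' @return A tibble with columns `lag` (steps), `t` (s), `mse_empirical`
#'   and `mse_model`, with the fitted per-step `mu_step` and `sigma_step`
#'   as attributes.
#' @export
brownian_error_stats <- function(err, dt = 0.05) {
  if (!is.matrix(err) || nrow(err) < 2) {
    stop("need a trials x time error matrix with at least 2 trials",
         call. = FALSE)
  }
  inc <- t(apply(cbind(0, err), 1, diff))
  mu <- mean(inc)
  sg <- stats::sd(inc)
  lag <- seq_len(ncol(err))
  out <- tibble::tibble(
    lag = lag,
    t = lag * dt,
    mse_empirical = colMeans(err^2),
    mse_model = lag * sg^2 + (lag * mu)^2
  )
  attr(out, "mu_step") <- mu
  attr(out, "sigma_step") <- sg
  out
}
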