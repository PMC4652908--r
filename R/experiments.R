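#' Default experiment configuration
#'
#' One nested list holding every model parameter at its default value: the
#' arena geometry, the trajectory movement statistics, the regularization of
#' the static system, both grid-model parameter sets, the two noise
#' parameterizations (bias-free and biased) and the analysis settings.
#' Experiment runners resolve their parameters from such a list, and every
#' run can write the resolved configuration beside its outputs
#' ([write_config()]).
#'
#' @return Nested named list; see the vignette for the meaning and units of
#'   each block.
#' @examples
#' cfg <- default_config()
#' cfg$trajectory$rayleigh_peak
#' @export
default_config <- function() {
  list(
    environment = list(width_x = 150, length_y_a = 150, length_y_b = 100,
                       wall_height = 50, eye_height = 2.5,
                       features_per_surface = 9),
    trajectory = list(rayleigh_peak = 13.25, yaw_mean = 0, yaw_sd = 337.93,
                      f_sample = 20, n_sample = 50000, min_speed = 5,
                      collision_distance = 15, x0 = 1, y0 = 1, phi0 = 0),
    static = list(alpha = 1e-4),
    vco = list(f = 7.38, beta_moving = 0.004, beta_static = 0.003,
               threshold = 1.8),
    attractor = list(n_x = 9, n_y = 10, I = 0.3, T_inhib = 0.05,
                     alpha_moving = 1.4e-3, alpha_static = 0.9e-3,
                     sigma = 0.24, gamma = 0, tau = 0.8, eta = 0.1),
    noise = list(
      bias_free = list(velocity = list(mean = 0, sd = 1.75),
                       angle = list(mean = 0, sd = 1)),
      biased = list(velocity = list(mean = 1, sd = 1.75),
                    angle = list(mean = 0.8, sd = 1))
    ),
    analysis = list(bin = 3, smooth = 3, occupancy_min = 0.1,
                    scan_from = -20, scan_to = 120, scan_step = 0.5,
                    shift = 50),
    n_trials = 100
  )
}

#' Read / write an experiment configuration as YAML
#'
#' @param path File path.
#' @param config Configuration list (see [default_config()]).
#' @return `read_config()` returns the configuration list, with any block
#'   missing from the file filled in from the defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

cfg_movement_params <- function(config) {
  tr <- config$trajectory
  movement_params(rayleigh_peak = tr$rayleigh_peak, yaw_mean = tr$yaw_mean,
                  yaw_sd = tr$yaw_sd, f_sample = tr$f_sample,
                  n_sample = tr$n_sample, min_speed = tr$min_speed,
                  collision_distance = tr$collision_distance)
}

cfg_environment <- function(config, seed) {
  ev <- config$environment
  build_environment(
    box_config("A", width_x = ev$width_x, wall_height = ev$wall_height,
               eye_height = ev$eye_height,
               features_per_surface = ev$features_per_surface),
    seed = seed
  )
}

# Independent sub-seeds derived from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1, n)
}

#' Run the barrier-compression experiment end to end
#'
#' Reproduces the box-compression protocol: forage in the square
#' configuration-A box and in the compressed configuration-B box, estimate
#' location with both feature systems, drive a grid model with each
#' estimate, build rate maps on the true positions and scan for the
#' compression percentage that best matches each B map to its A map. The
#' moving feature system's map needs essentially no rescaling (its optic
#' flow input ignores wall positions); the static feature system's map must
#' be expanded by close to the full barrier shift.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Master seed; independent streams are derived for the
#'   environment, each trajectory and the grid models.
#' @param grid_model `"vco"` or `"attractor"`.
#' @param out_dir Optional directory: scans, the summary and the resolved
#'   configuration (with the seed) are written there as CSV/YAML.
#' @return List with `summary` (tibble: system, grid model, argmax percent,
#'   peak r^2), `scans` (named list of [compression_scan()] results), `maps`
#'   (named list of [rate_map()]s) and `estimates` (named list of location
#'   estimate series).
#' @export
run_compression_experiment <- function(config = default_config(), seed = 1,
                                       grid_model = c("vco", "attractor"),
                                       out_dir = NULL) {
  grid_model <- match.arg(grid_model)
  seeds <- derive_seeds(seed, 4)
  env <- cfg_environment(config, seeds[1])
  mp <- cfg_movement_params(config)
  tr <- config$trajectory
  an <- config$analysis

  trajs <- list(
    A = synthesize_trajectory(env, mp, seed = seeds[2], config = "A",
                              x0 = tr$x0, y0 = tr$y0, phi0 = tr$phi0),
    B = synthesize_trajectory(env, mp, seed = seeds[3], config = "B",
                              x0 = tr$x0, y0 = tr$y0, phi0 = tr$phi0)
  )
  estimates <- list()
  maps <- list()
  for (cfg_label in c("A", "B")) {
    traj <- trajs[[cfg_label]]
    estimates[[paste0("moving_", cfg_label)]] <-
      estimate_path_moving(traj, env, cfg_label)
    estimates[[paste0("static_", cfg_label)]] <-
      estimate_path_static(traj, env, cfg_label, alpha = config$static$alpha)
  }
  for (system in c("moving", "static")) {
    for (cfg_label in c("A", "B")) {
      est <- estimates[[paste0(system, "_", cfg_label)]]
      spikes <- if (grid_model == "vco") {
        beta <- if (system == "moving") config$vco$beta_moving else
          config$vco$beta_static
        vco_spikes(est, vco_params(f = config$vco$f, beta = beta,
                                   threshold = config$vco$threshold))
      } else {
        at <- config$attractor
        alpha <- if (system == "moving") at$alpha_moving else at$alpha_static
        attractor_spikes(location_velocity(est),
                         attractor_params(n_x = at$n_x, n_y = at$n_y,
                                          I = at$I, T_inhib = at$T_inhib,
                                          alpha = alpha, sigma = at$sigma,
                                          gamma = at$gamma, tau = at$tau,
                                          eta = at$eta),
                         seed = seeds[4])
      }
      maps[[paste0(system, "_", cfg_label)]] <-
        rate_map(spikes, trajs[[cfg_label]], bin = an$bin, smooth = an$smooth,
                 occupancy_min = an$occupancy_min)
    }
  }
  scans <- list(
    moving = compression_scan(maps$moving_A, maps$moving_B, axis = "y",
                              range = c(an$scan_from, an$scan_to),
                              step = an$scan_step, shift = an$shift),
    static = compression_scan(maps$static_A, maps$static_B, axis = "y",
                              range = c(an$scan_from, an$scan_to),
                              step = an$scan_step, shift = an$shift)
  )
  summary <- dplyr::bind_rows(
    dplyr::mutate(glance(scans$moving), system = "moving", .before = 1),
    dplyr::mutate(glance(scans$static), system = "static", .before = 1)
  )
  summary$grid_model <- grid_model
  out <- list(summary = summary, scans = scans, maps = maps,
              estimates = estimates, config = config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "compression_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(scans$moving, file.path(out_dir, "scan_moving.csv"),
                     row.names = FALSE)
    utils::write.csv(scans$static, file.path(out_dir, "scan_static.csv"),
                     row.names = FALSE)
    write_config(c(config, list(seed = seed, grid_model = grid_model)),
                 file.path(out_dir, "config_resolved.yaml"))
  }
  out
}

#' Noise trials of the moving feature system
#'
#' Repeats the noisy optic-flow pipeline on one fixed trajectory: the clean
#' ground-feature flow is computed once, and each trial superimposes fresh
#' angular-velocity noise, re-estimates the per-step velocities and
#' accumulates three error signals -- the Euclidean error of the
#' Cartesian-integrated position, and the directly integrated radial
#' distance and angle errors that feed [brownian_error_stats()].
#'
#' @param traj Trajectory the trials share.
#' @param env Environment observed.
#' @param spec [noise_spec()] with domain `"angular_velocity"`.
#' @param n_trials Number of independent noise realizations.
#' @param seed Master seed for the trial noise streams.
#' @param config "A" or "B".
#' @return List of three `n_trials x (n-1)` matrices: `eucl` (cm),
#'   `l_err` (cm), `phi_err` (rad), plus `dt`.
#' @export
moving_noise_trials <- function(traj, env, spec, n_trials = 100, seed = 1,
                                config = "A") {
  stopifnot(inherits(spec, "noise_spec"), spec$domain == "angular_velocity")
  box <- env_config(env, config)
  gf <- ground_flow_matrices(traj, env, config)
  dt <- 1 / attr(traj, "f_sample")
  n <- nrow(traj)
  mu <- spec$mean * pi / 180
  sg <- spec$sd * pi / 180
  seeds <- derive_seeds(seed, n_trials)
  eucl <- matrix(0, n_trials, n - 1)
  l_err <- matrix(0, n_trials, n - 1)
  phi_err <- matrix(0, n_trials, n - 1)
  for (k in seq_len(n_trials)) {
    set.seed(seeds[k])
    td <- gf$theta_dot + matrix(stats::rnorm(length(gf$theta_dot), mu, sg),
                                n - 1)
    pd <- gf$phi_dot + matrix(stats::rnorm(length(gf$phi_dot), mu, sg),
                              n - 1)
    est <- estimate_velocity_batch(gf$theta, gf$phi, td, pd, gf$mask,
                                   box$eye_height)
    path <- integrate_path(est$v, est$omega, x0 = traj$x[1], y0 = traj$y[1],
                           phi0 = traj$phi[1], dt = dt)
    eucl[k, ] <- sqrt((path$x_hat[-1] - traj$x[-1])^2 +
                        (path$y_hat[-1] - traj$y[-1])^2)
    l_err[k, ] <- dt * cumsum(gf$v_true - est$v)
    phi_err[k, ] <- dt * cumsum(gf$omega_true - est$omega)
  }
  list(eucl = eucl, l_err = l_err, phi_err = phi_err, dt = dt)
}

#' Noise trials of the static feature system
#'
#' Repeats the noisy triangulation pipeline on one fixed trajectory: the
#' clean wall-landmark bearings are computed once, each trial superimposes
#' fresh angle noise and re-triangulates every sample independently,
#' recording the Euclidean error of the rescaled location estimate. Because
#' the estimate is frame-by-frame, the error time series is stationary --
#' there is nothing to accumulate.
#'
#' @inheritParams moving_noise_trials
#' @param spec [noise_spec()] with domain `"angle"`.
#' @param alpha Regularization of the triangulation.
#' @return List with `eucl` (`n_trials x n` matrix, cm) and `dt`.
#' @export
static_noise_trials <- function(traj, env, spec, n_trials = 100, seed = 1,
                                config = "A", alpha = 1e-4) {
  stopifnot(inherits(spec, "noise_spec"), spec$domain == "angle")
  wa <- wall_angle_matrices(traj, env, config)
  mem_box <- env_config(env, "A")
  mu <- spec$mean * pi / 180
  sg <- spec$sd * pi / 180
  seeds <- derive_seeds(seed, n_trials)
  n <- nrow(traj)
  eucl <- matrix(0, n_trials, n)
  for (k in seq_len(n_trials)) {
    set.seed(seeds[k])
    psi <- wa$bearing + matrix(stats::rnorm(length(wa$bearing), mu, sg),
                               n)
    sol <- triangulate_batch(psi, wa$mask, wa$surface, wa$mem_x, wa$mem_y,
                             L = mem_box$length_y, W = mem_box$width_x,
                             alpha = alpha)
    eucl[k, ] <- sqrt((sol$x / sol$eta - traj$x)^2 +
                        (sol$y / sol$xi - traj$y)^2)
  }
  list(eucl = eucl, dt = 1 / attr(traj, "f_sample"))
}

#' Run the noise experiment end to end
#'
#' Reproduces the noise study on the configuration-A trajectory: matched
#' signal-to-noise ratios for the two noise parameterizations in both
#' domains, across-trial Euclidean-error bands for the four cells of the
#' design (bias-free/biased x moving/static), Brownian-motion statistics of
#' the directly integrated distance and angle errors, and single-trial rate
#' maps with gridness scores for each cell.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Master seed.
#' @param n_trials Trials for the error statistics (the rate maps use one).
#' @param grid_model `"vco"` or `"attractor"`.
#' @param out_dir Optional output directory for CSV summaries and the
#'   resolved configuration.
#' @return List with `snr` (tibble: parameterization, domain/system, dB),
#'   `bands` (named list of [error_band()] tibbles), `brownian` (named list
#'   of [brownian_error_stats()] tibbles for the bias-free and biased
#'   velocity noise), `maps` and `gridness` for the four design cells.
#' @export
run_noise_experiment <- function(config = default_config(), seed = 1,
                                 n_trials = config$n_trials,
                                 grid_model = c("vco", "attractor"),
                                 out_dir = NULL) {
  grid_model <- match.arg(grid_model)
  seeds <- derive_seeds(seed, 12)
  env <- cfg_environment(config, seeds[1])
  tr <- config$trajectory
  traj <- synthesize_trajectory(env, cfg_movement_params(config),
                                seed = seeds[2], config = "A",
                                x0 = tr$x0, y0 = tr$y0, phi0 = tr$phi0)
  nz <- config$noise
  specs <- list(
    bias_free_velocity = noise_spec("angular_velocity",
                                    nz$bias_free$velocity$mean,
                                    nz$bias_free$velocity$sd),
    bias_free_angle = noise_spec("angle", nz$bias_free$angle$mean,
                                 nz$bias_free$angle$sd),
    biased_velocity = noise_spec("angular_velocity", nz$biased$velocity$mean,
                                 nz$biased$velocity$sd),
    biased_angle = noise_spec("angle", nz$biased$angle$mean,
                              nz$biased$angle$sd)
  )
  snr <- tibble::tibble(
    parameterization = c("bias-free", "bias-free", "biased", "biased"),
    system = c("moving", "static", "moving", "static"),
    domain = c("angular_velocity", "angle", "angular_velocity", "angle"),
    snr_db = c(
      observation_snr(traj, env, specs$bias_free_velocity, seed = seeds[3]),
      observation_snr(traj, env, specs$bias_free_angle, seed = seeds[4]),
      observation_snr(traj, env, specs$biased_velocity, seed = seeds[5]),
      observation_snr(traj, env, specs$biased_angle, seed = seeds[6])
    )
  )

  mv_free <- moving_noise_trials(traj, env, specs$bias_free_velocity,
                                 n_trials, seed = seeds[7])
  mv_bias <- moving_noise_trials(traj, env, specs$biased_velocity,
                                 n_trials, seed = seeds[8])
  st_free <- static_noise_trials(traj, env, specs$bias_free_angle,
                                 n_trials, seed = seeds[9],
                                 alpha = config$static$alpha)
  st_bias <- static_noise_trials(traj, env, specs$biased_angle,
                                 n_trials, seed = seeds[10],
                                 alpha = config$static$alpha)
  bands <- list(
    moving_bias_free = error_band(mv_free$eucl, t = traj$t[-1]),
    moving_biased = error_band(mv_bias$eucl, t = traj$t[-1]),
    static_bias_free = error_band(st_free$eucl, t = traj$t),
    static_biased = error_band(st_bias$eucl, t = traj$t)
  )
  brownian <- list(
    distance_bias_free = brownian_error_stats(mv_free$l_err, mv_free$dt),
    angle_bias_free = brownian_error_stats(mv_free$phi_err, mv_free$dt),
    distance_biased = brownian_error_stats(mv_bias$l_err, mv_bias$dt),
    angle_biased = brownian_error_stats(mv_bias$phi_err, mv_bias$dt)
  )

  # single-trial grid maps for the four design cells
  maps <- list()
  scores <- list()
  an <- config$analysis
  cells <- list(
    moving_bias_free = list(system = "moving", spec = specs$bias_free_velocity),
    static_bias_free = list(system = "static", spec = specs$bias_free_angle),
    moving_biased = list(system = "moving", spec = specs$biased_velocity),
    static_biased = list(system = "static", spec = specs$biased_angle)
  )
  for (nm in names(cells)) {
    cl <- cells[[nm]]
    est <- if (cl$system == "moving") {
      estimate_path_moving(traj, env, "A", noise = cl$spec, seed = seeds[11])
    } else {
      estimate_path_static(traj, env, "A", noise = cl$spec, seed = seeds[12],
                           alpha = config$static$alpha)
    }
    spikes <- if (grid_model == "vco") {
      beta <- if (cl$system == "moving") config$vco$beta_moving else
        config$vco$beta_static
      vco_spikes(est, vco_params(f = config$vco$f, beta = beta,
                                 threshold = config$vco$threshold))
    } else {
      at <- config$attractor
      alpha <- if (cl$system == "moving") at$alpha_moving else at$alpha_static
      attractor_spikes(location_velocity(est),
                       attractor_params(n_x = at$n_x, n_y = at$n_y, I = at$I,
                                        T_inhib = at$T_inhib, alpha = alpha,
                                        sigma = at$sigma, gamma = at$gamma,
                                        tau = at$tau, eta = at$eta),
                       seed = seeds[11])
    }
    maps[[nm]] <- rate_map(spikes, traj, bin = an$bin, smooth = an$smooth,
                           occupancy_min = an$occupancy_min)
    scores[[nm]] <- tryCatch(gridness(maps[[nm]]), error = function(e) NA_real_)
  }

  out <- list(snr = snr, bands = bands, brownian = brownian, maps = maps,
              gridness = tibble::tibble(cell = names(scores),
                                        gridness = unlist(scores)),
              config = config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(snr, file.path(out_dir, "snr_table.csv"),
                     row.names = FALSE)
    utils::write.csv(out$gridness, file.path(out_dir, "gridness.csv"),
                     row.names = FALSE)
    for (nm in names(bands)) {
      utils::write.csv(bands[[nm]],
                       file.path(out_dir, paste0("error_band_", nm, ".csv")),
                       row.names = FALSE)
    }
    write_config(c(config, list(seed = seed, n_trials = n_trials)),
                 file.path(out_dir, "config_resolved.yaml"))
  }
  out
}
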