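make_ground_obs <- function(pose, v_z, omega_y, env = test_env(seed = 2)) {
  ground <- env_features(env, "A")
  ground <- ground[ground$surface == "ground", ]
  obs <- project_features(ground[, c("x", "y", "z")],
                          pose$x, pose$y, pose$phi)
  flow_ground(obs, v_z = v_z, omega_y = omega_y)
}

test_that("self-motion is recovered exactly from noise-free flow", {
  poses <- random_poses(6, seed = 11)
  cases <- list(c(13, 0.5), c(2, -3), c(25, 0), c(8, 1.2))
  for (i in seq_len(nrow(poses))) {
    for (cs in cases) {
      obs <- make_ground_obs(poses[i, ], cs[1], cs[2])
      est <- estimate_velocity(obs)
      expect_equal(est$v_z_hat, cs[1], tolerance = 1e-10)
      expect_equal(est$omega_y_hat, cs[2], tolerance = 1e-10)
    }
  }
})

test_that("pure rotation yields zero forward speed", {
  est <- estimate_velocity(make_ground_obs(random_poses(1, seed = 3), 0, 0.9))
  expect_equal(est$v_z_hat, 0, tolerance = 1e-10)
  expect_equal(est$omega_y_hat, 0.9, tolerance = 1e-10)
})

test_that("the closed form agrees with brute-force minimization of the functional", {
  pose <- random_poses(1, seed = 13)
  obs <- make_ground_obs(pose, 11, -0.6)
  set.seed(14)
  obs$azimuth_rate <- obs$azimuth_rate + rnorm(nrow(obs), 0, 0.05)
  obs$elevation_rate <- obs$elevation_rate + rnorm(nrow(obs), 0, 0.05)
  d <- 2.5
  g <- -sin(obs$azimuth) * sin(obs$elevation) / (d * cos(obs$elevation))
  h <- -cos(obs$azimuth) * sin(obs$elevation)^2 / d
  F_fun <- function(p) {
    sum((obs$azimuth_rate - g * p[1] + p[2])^2 +
          (obs$elevation_rate - h * p[1])^2)
  }
  # coarse grid then local refinement, independent of the normal equations
  grid <- expand.grid(v = seq(0, 20, by = 0.5), w = seq(-2, 2, by = 0.1))
  start <- grid[which.min(apply(grid, 1, F_fun)), ]
  opt <- optim(as.numeric(start), F_fun, method = "BFGS",
               control = list(reltol = 1e-14))
  est <- estimate_velocity(obs)
  expect_equal(est$v_z_hat, opt$par[1], tolerance = 1e-6)
  expect_equal(est$omega_y_hat, opt$par[2], tolerance = 1e-6)
  expect_lte(F_fun(c(est$v_z_hat, est$omega_y_hat)), opt$value + 1e-10)
})

test_that("degenerate flow geometries raise errors", {
  obs <- tibble::tibble(azimuth = 0.3, elevation = -0.2,
                        azimuth_rate = 0, elevation_rate = 0)
  expect_error(estimate_velocity(obs), "at least 2")
  flat <- tibble::tibble(azimuth = c(0.1, 0.5), elevation = c(-1e-9, 1e-9),
                         azimuth_rate = c(0, 0), elevation_rate = c(0, 0))
  expect_error(estimate_velocity(flat), "singular|degenerate")
})

test_that("path integration reproduces simple closed forms", {
  still <- integrate_path(rep(0, 50), rep(0, 50), x0 = 3, y0 = 4)
  expect_true(all(still$x_hat == 3 & still$y_hat == 4))
  # 10 cm/s straight ahead for 1 s at 20 Hz
  straight <- integrate_path(rep(10, 20), rep(0, 20), dt = 0.05)
  expect_equal(tail(straight$x_hat, 1), 10)
  expect_equal(tail(straight$y_hat, 1), 0)
  expect_error(integrate_path(1:5, 1:4), "same length")
})

test_that("noise-free pipeline reproduces the trajectory to numerical precision", {
  env <- test_env()
  for (config in c("A", "B")) {
    traj <- test_traj(env, n = 4000, seed = 22, config = config)
    est <- estimate_path_moving(traj, env, config)
    err <- euclidean_error(est, traj)
    expect_lt(max(err$error), 1e-6)  # far below the 1 cm end-to-end bound
  }
})

test_that("per-step velocity errors are zero-mean under bias-free noise", {
  env <- test_env()
  traj <- test_traj(env, n = 1500, seed = 23)
  spec <- noise_spec("angular_velocity", mean = 0, sd = 1.75)
  trials <- moving_noise_trials(traj, env, spec, n_trials = 120, seed = 3)
  # per-step distance-error increments pool across trials and steps
  inc <- t(apply(cbind(0, trials$l_err), 1, diff))
  expect_lt(abs(mean(inc)), 3 * sd(inc) / sqrt(length(inc)) + 1e-4)
  winc <- t(apply(cbind(0, trials$phi_err), 1, diff))
  expect_lt(abs(mean(winc)), 3 * sd(winc) / sqrt(length(winc)) + 1e-6)
})

test_that("moving-system estimates ignore the barrier shift", {
  env <- test_env()
  trajB <- test_traj(env, n = 3000, seed = 24, config = "B")
  est <- estimate_path_moving(trajB, env, "B")
  # tracks the true, compressed-range positions: same range as the truth
  expect_lt(max(abs(est$y_hat - trajB$y)), 1e-6)
  expect_lte(max(est$y_hat), 100 + 1e-6)
})
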