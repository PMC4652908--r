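test_that("spherical projection handles canonical directions", {
  p <- project_features(data.frame(X = 0, Y = 0, Z = 100))
  expect_equal(c(p$azimuth, p$elevation), c(0, 0))
  p <- project_features(data.frame(X = 100, Y = 0, Z = 0))
  expect_equal(c(p$azimuth, p$elevation), c(pi / 2, 0))
  p <- project_features(data.frame(X = 0, Y = -2.5, Z = 2.5))
  expect_equal(c(p$azimuth, p$elevation), c(0, -pi / 4))
  # angles are invariant to distance
  p1 <- project_features(data.frame(X = 3, Y = -1, Z = 5))
  p2 <- project_features(data.frame(X = 30, Y = -10, Z = 50))
  expect_equal(p1$azimuth, p2$azimuth)
  expect_equal(p1$elevation, p2$elevation)
  expect_error(project_features(data.frame(X = 0, Y = 0, Z = 0)), "origin")
})

test_that("world/camera frame conversions invert each other", {
  poses <- random_poses(10, seed = 5)
  set.seed(6)
  pts <- tibble::tibble(x = runif(20, 0, 150), y = runif(20, 0, 150),
                        z = runif(20, 0, 50))
  for (i in seq_len(nrow(poses))) {
    cam <- world_to_camera(pts, poses$x[i], poses$y[i], poses$phi[i])
    back <- camera_to_world(cam, poses$x[i], poses$y[i], poses$phi[i])
    expect_equal(back$x, pts$x, tolerance = 1e-12)
    expect_equal(back$y, pts$y, tolerance = 1e-12)
    expect_equal(back$z, pts$z, tolerance = 1e-12)
  }
})

test_that("plane distance matches the closed form and its scalings", {
  # 45 degrees below the axis at eye height 2.5: straight-line distance by
  # Pythagoras is 2.5 * sqrt(2)
  expect_equal(ground_distance(0, -pi / 4, offset = 2.5), 2.5 * sqrt(2))
  # linear in the offset at fixed angles
  expect_equal(ground_distance(0.4, -0.3, offset = 5),
               2 * ground_distance(0.4, -0.3, offset = 2.5))
  # horizon direction is degenerate
  expect_warning(d <- ground_distance(0, 0, offset = 2.5), "grazing")
  expect_identical(d, Inf)
  # agrees with the camera-frame geometry of an actual ground point
  prj <- project_features(data.frame(X = 10, Y = -2.5, Z = 40))
  expect_equal(ground_distance(prj$azimuth, prj$elevation, offset = 2.5),
               prj$distance)
})

test_that("analytic ground flow matches central finite differences of the projection", {
  env <- test_env(seed = 3)
  ground <- env_features(env, "A")
  ground <- ground[ground$surface == "ground", ]
  poses <- random_poses(8, seed = 7)
  h <- 1e-5
  for (i in seq_len(nrow(poses))) {
    v_z <- 5 + 10 * i / 8
    w <- (-1)^i * (0.2 + 0.1 * i)
    pose_at <- function(s) {
      phi_s <- poses$phi[i] + w * s
      list(x = poses$x[i] + v_z * s * cos(phi_s),
           y = poses$y[i] + v_z * s * sin(phi_s),
           phi = phi_s)
    }
    ang <- function(s) {
      p <- pose_at(s)
      project_features(ground[, c("x", "y", "z")], p$x, p$y, p$phi)
    }
    a_plus <- ang(h); a_minus <- ang(-h)
    fd_az <- wrap_angle(a_plus$azimuth - a_minus$azimuth) / (2 * h)
    fd_el <- (a_plus$elevation - a_minus$elevation) / (2 * h)
    obs <- ang(0)
    fl <- flow_ground(obs, v_z = v_z, omega_y = w)
    expect_equal(fl$azimuth_rate, fd_az, tolerance = 1e-5)
    expect_equal(fl$elevation_rate, fd_el, tolerance = 1e-5)
  }
})

test_that("general six-component flow reduces to the ground-plane flow", {
  env <- test_env(seed = 4)
  ground <- env_features(env, "A")
  ground <- ground[ground$surface == "ground", ]
  poses <- random_poses(5, seed = 9)
  for (i in seq_len(nrow(poses))) {
    obs <- project_features(ground[, c("x", "y", "z")],
                            poses$x[i], poses$y[i], poses$phi[i])
    g1 <- flow_ground(obs, v_z = 12, omega_y = -0.7)
    g2 <- flow_general(obs, v = c(0, 0, 12), omega = c(0, -0.7, 0))
    expect_equal(g1$azimuth_rate, g2$azimuth_rate, tolerance = 1e-10)
    expect_equal(g1$elevation_rate, g2$elevation_rate, tolerance = 1e-10)
  }
})

test_that("pure rotation sweeps all azimuths at -omega and leaves elevation still", {
  obs <- tibble::tibble(azimuth = seq(-3, 3, by = 0.5),
                        elevation = rep(-0.4, 13), distance = 10)
  fl <- flow_ground(obs, v_z = 0, omega_y = 0.8)
  expect_equal(fl$azimuth_rate, rep(-0.8, 13))
  expect_equal(fl$elevation_rate, rep(0, 13))
})

test_that("the worked flow example matches the finite-difference sign", {
  # feature straight ahead, 45 degrees down, eye height 2.5, approach at
  # 10 cm/s: the feature dips downward, elevation rate -2 rad/s
  fl <- flow_ground(tibble::tibble(azimuth = 0, elevation = -pi / 4),
                    v_z = 10, omega_y = 0, d = 2.5)
  expect_equal(fl$elevation_rate, -2)
  expect_equal(fl$azimuth_rate, 0)
  # features at the horizon are degenerate
  expect_error(flow_ground(tibble::tibble(azimuth = 0, elevation = 0),
                           v_z = 1, omega_y = 0), "horizon")
})
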