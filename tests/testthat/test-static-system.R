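test_that("wall angles transform by the per-wall convention", {
  obs <- data.frame(surface = c("N-wall", "S-wall", "W-wall", "E-wall"),
                    azimuth = c(0.3, 0.3, pi / 2, 0.2))
  tw <- transform_wall_angles(obs)
  expect_equal(tw$theta, c(0.3, -0.3, 0, wrap_angle(-0.2 - pi / 2)))
  expect_equal(tw$wall, c("N", "S", "W", "E"))
  # re-referencing through the heading shifts the bearing
  tw2 <- transform_wall_angles(obs[1, ], heading = 0.5)
  expect_equal(tw2$bearing, 0.8)
  expect_error(transform_wall_angles(data.frame(surface = "ground",
                                                azimuth = 0)), "wall")
})

test_that("self-consistent observations give the exact location and unit factors", {
  for (pos in list(c(60, 90), c(20, 20), c(110, 40))) {
    walls <- compressed_scene(pos[1], pos[2], cy = 1, cx = 1, seed = 4)
    sol <- triangulate(walls)
    expect_equal(sol$x_hat, pos[1], tolerance = 1e-8)
    expect_equal(sol$y_hat, pos[2], tolerance = 1e-8)
    expect_equal(sol$eta_hat, 1, tolerance = 1e-8)
    expect_equal(sol$xi_hat, 1, tolerance = 1e-8)
  }
})

test_that("a 2/3-compressed box is resolved as xi = 2/3 with rescaled location", {
  walls <- compressed_scene(75, 50, cy = 2 / 3, seed = 5)
  sol <- triangulate(walls)
  expect_equal(sol$xi_hat, 2 / 3, tolerance = 1e-8)
  expect_equal(sol$eta_hat, 1, tolerance = 1e-8)
  # the rat at the true center of the compressed box reads out the center of
  # the remembered box
  expect_equal(sol$x_hat, 75, tolerance = 1e-8)
  expect_equal(sol$y_hat, 75, tolerance = 1e-8)
})

test_that("the 4x4 closed form matches brute-force minimization of the functional", {
  set.seed(8)
  for (rep in 1:4) {
    xs <- runif(1, 25, 125); ys <- runif(1, 25, 125)
    cy <- runif(1, 0.6, 1)
    walls <- compressed_scene(xs, ys, cy = cy, seed = rep)
    walls$bearing <- walls$bearing + rnorm(nrow(walls), 0, 0.02)
    sol <- triangulate(walls)
    oracle <- minimize_functional(
      walls, start = c(xs + 2, ys - 3, 1.05, cy + 0.05,
                       rep(60, nrow(walls))))
    expect_equal(sol$x_s_hat, oracle$par[1], tolerance = 1e-3)
    expect_equal(sol$y_s_hat, oracle$par[2], tolerance = 1e-3)
    expect_equal(sol$eta_hat, oracle$par[3], tolerance = 1e-3)
    expect_equal(sol$xi_hat, oracle$par[4], tolerance = 1e-3)
    # and the closed form is at least as good a minimum
    lam <- attr(sol, "lambda")
    expect_lte(oracle$E(c(sol$x_s_hat, sol$y_s_hat, sol$eta_hat, sol$xi_hat,
                          lam)),
               oracle$value * (1 + 1e-6) + 1e-12)
  }
})

test_that("imposed compressions over 0.6..1 are recovered by xi and fill the range", {
  for (cc in c(0.6, 0.8, 1)) {
    xis <- sapply(list(c(40, 30), c(75, 60), c(110, 80), c(30, 85 * cc)),
                  function(p) {
                    walls <- compressed_scene(p[1], p[2] * cc, cy = cc, seed = 6)
                    triangulate(walls)$xi_hat
                  })
    expect_equal(median(xis), cc, tolerance = 1e-6)
    # a rat at the compressed far edge reads out the remembered far edge
    walls <- compressed_scene(75, cc * 150 - 1, cy = cc, seed = 6)
    expect_equal(triangulate(walls)$y_hat, (cc * 150 - 1) / cc,
                 tolerance = 1e-6)
  }
})

test_that("the regularization weight does not move consistent solutions", {
  walls <- compressed_scene(45, 95, cy = 1, seed = 9)
  s1 <- triangulate(walls, alpha = 1e-4)
  s2 <- triangulate(walls, alpha = 1e-9)
  expect_equal(s1$x_hat, s2$x_hat, tolerance = 1e-6)
  expect_equal(s1$y_hat, s2$y_hat, tolerance = 1e-6)
})

test_that("estimates are frame-by-frame: one perturbed sample moves one estimate", {
  env <- test_env()
  traj <- test_traj(env, n = 300, seed = 31)
  base <- estimate_path_static(traj, env, "A")
  wa <- twostream:::wall_angle_matrices(traj, env, "A")
  psi <- wa$bearing
  psi[150, ] <- psi[150, ] + 0.05
  box <- env_config(env, "A")
  sol <- twostream:::triangulate_batch(psi, wa$mask, wa$surface, wa$mem_x,
                                       wa$mem_y, L = box$length_y,
                                       W = box$width_x, alpha = 1e-4)
  moved <- abs(sol$x / sol$eta - base$x_hat) +
    abs(sol$y / sol$xi - base$y_hat)
  expect_gt(moved[150], 1e-6)
  expect_lt(max(moved[-150]), 1e-9)
})

test_that("static estimates in configuration B fill the remembered box", {
  env <- test_env()
  trajB <- test_traj(env, n = 2000, seed = 32, config = "B")
  est <- estimate_path_static(trajB, env, "B")
  expect_equal(median(est$xi_hat), 2 / 3, tolerance = 1e-6)
  expect_equal(est$y_hat, trajB$y * 1.5, tolerance = 1e-6)
  expect_equal(est$x_hat, trajB$x, tolerance = 1e-4)
})

test_that("triangulation demands all four walls", {
  walls <- compressed_scene(75, 75, seed = 2)
  expect_error(triangulate(walls[walls$wall != "N", ]), "four walls")
})
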