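test_that("a stationary VCO cell fires periodically at the theta frequency", {
  loc <- tibble::tibble(t = seq(0, 10, by = 0.002), x = 0, y = 0)
  sp <- vco_spikes(loc, vco_params())
  # at the origin the product is (2 cos(wt))^3: bursts at every theta cycle
  burst_starts <- which(diff(c(0, sp$spike)) == 1)
  intervals <- diff(loc$t[burst_starts])
  expect_equal(mean(intervals), 1 / 7.38, tolerance = 0.01)
  # and the pattern is threshold-consistent with the closed form
  prod3 <- (2 * cos(2 * pi * 7.38 * loc$t))^3
  expect_equal(sp$spike, as.integer(prod3 > 1.8))
})

test_that("translating locations by a lattice period leaves VCO spikes unchanged", {
  p <- vco_params(beta = 0.004)
  period <- 2 / (p$beta * p$f)  # lattice period along a basis vector
  set.seed(5)
  loc <- tibble::tibble(t = seq(0, 20, by = 0.05),
                        x = cumsum(rnorm(401, 0, 2)),
                        y = cumsum(rnorm(401, 0, 2)))
  s1 <- vco_spikes(loc, p)
  s2 <- vco_spikes(dplyr::mutate(loc, x = x + period), p)
  expect_identical(s1$spike, s2$spike)
  # a translation by half that period does change the pattern
  s3 <- vco_spikes(dplyr::mutate(loc, x = x + period / 3), p)
  expect_false(identical(s1$spike, s3$spike))
})

test_that("VCO band spacing along a basis vector is 1 / (beta f)", {
  p <- vco_params(beta = 0.004)
  # sweep slowly along the first basis vector; bands appear wherever the
  # location-driven oscillation re-aligns with theta
  speed <- 2
  loc <- tibble::tibble(t = seq(0, 150, by = 0.0025))
  loc$x <- speed * loc$t
  loc$y <- 0
  sp <- vco_spikes(loc, p)
  xs <- loc$x[sp$spike == 1]
  h <- hist(xs, breaks = seq(0, 305, by = 1), plot = FALSE)
  dens <- h$counts
  # spectral peak of the band pattern
  spec <- Mod(fft(dens - mean(dens)))[2:150]
  freq <- (2:150 - 1) / length(dens)
  spacing <- 1 / freq[which.max(spec)]
  expect_equal(spacing, 1 / (p$beta * p$f), tolerance = 0.05)
})

test_that("attractor weights are symmetric at rest and activities stay valid", {
  p <- attractor_params()
  geo <- twostream:::torus_geometry(p)
  dx <- outer(geo$cells[, 1], geo$cells[, 1], "-")
  dy <- outer(geo$cells[, 2], geo$cells[, 2], "-")
  d2 <- twostream:::torus_dist2(dx, dy, 0, 0, geo$shifts)
  W <- p$I * exp(-d2 / p$sigma^2) - p$T_inhib
  expect_equal(W, t(W), tolerance = 1e-12)
  vel <- tibble::tibble(t = seq(0.05, 10, by = 0.05), vx = 0, vy = 0)
  sp <- attractor_spikes(vel, p, seed = 2)
  a <- attr(sp, "activity")
  expect_true(all(a >= 0))
  expect_true(all(is.finite(a)))
  expect_gt(max(a), p$eta)  # a formed bump exceeds the spike threshold
})

test_that("the readout cell index follows the sheet dimensions", {
  expect_equal(attractor_params(n_x = 9, n_y = 10)$readout, 85)
  expect_equal(attractor_params(n_x = 10, n_y = 9)$readout, 86)
})

test_that("constant velocity moves the bump proportionally to the gain", {
  p <- attractor_params(alpha = 1.4e-3)
  geo <- twostream:::torus_geometry(p)
  centroid_x <- function(a) {
    # circular mean of the torus x coordinate weighted by activity
    ang <- 2 * pi * geo$cells[, 1]
    atan2(sum(a * sin(ang)), sum(a * cos(ang))) / (2 * pi)
  }
  run_shift <- function(v, steps) {
    vel <- tibble::tibble(t = seq_len(steps) * 0.05, vx = v, vy = 0)
    sp0 <- attractor_spikes(vel[1, ], p, seed = 7, burn_in = 300)
    a0 <- attr(sp0, "activity")
    sp1 <- attractor_spikes(vel, p, seed = 7, burn_in = 300)
    a1 <- attr(sp1, "activity")
    d <- (centroid_x(a1) - centroid_x(a0)) %% 1
    if (d > 0.5) d - 1 else d
  }
  d_slow <- run_shift(10, 100)
  d_fast <- run_shift(20, 100)
  expect_gt(abs(d_slow), 1e-3)
  # doubling the velocity doubles the drift along the same direction
  expect_equal(d_fast / d_slow, 2, tolerance = 0.25)
  # a larger input gain drifts the bump further for the same velocity
  p2 <- attractor_params(alpha = 2.8e-3)
  p_save <- p
  p <- p2
  d_gain <- run_shift(10, 100)
  p <- p_save
  expect_gt(abs(d_gain), abs(d_slow))
})

test_that("location differencing produces the attractor's velocity signal", {
  loc <- tibble::tibble(t = c(0, 0.05, 0.1), x_hat = c(0, 1, 3),
                        y_hat = c(0, -1, 1))
  v <- location_velocity(loc)
  expect_equal(v$vx, c(20, 40))
  expect_equal(v$vy, c(-20, 40))
  expect_error(attractor_spikes(tibble::tibble(t = 1, vx = NA, vy = 0)),
               "non-finite")
})
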