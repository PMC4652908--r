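test_that("uniform firing on uniform occupancy gives a flat map", {
  set.seed(1)
  n <- 20000
  traj <- tibble::tibble(t = (seq_len(n) - 1) * 0.05,
                         x = runif(n, 0, 60), y = runif(n, 0, 60))
  spikes <- tibble::tibble(t = traj$t, spike = 1L)
  m <- rate_map(spikes, traj, bin = 10, smooth = 0, occupancy_min = 0.05,
                extent = c(60, 60))
  expect_true(all(abs(m$rate - 20) < 1e-9))  # 1 spike per 50 ms bin visit
  # no spikes -> all-zero map
  m0 <- rate_map(dplyr::mutate(spikes, spike = 0L), traj, bin = 10,
                 smooth = 0, occupancy_min = 0.05, extent = c(60, 60))
  expect_true(all(m0$rate == 0))
})

test_that("empty trajectories and misaligned spike trains are rejected", {
  traj <- tibble::tibble(t = numeric(0), x = numeric(0), y = numeric(0))
  expect_error(rate_map(tibble::tibble(t = 0, spike = 1), traj), "empty")
  traj2 <- tibble::tibble(t = c(0, 0.05), x = c(1, 2), y = c(1, 2))
  expect_error(rate_map(tibble::tibble(t = 0.025, spike = 1), traj2),
               "align")
})

test_that("VCO firing on a real trajectory produces a hexagonal map at the implied spacing", {
  env <- test_env()
  traj <- test_traj(env, n = 20000, seed = 8)
  p <- vco_params(beta = 0.004)
  sp <- vco_spikes(traj, p)
  m <- rate_map(sp, traj)
  g <- gridness(m)
  expect_gt(g, 0.4)
  # autocorrelogram ring radius ~ grid spacing 2 / (sqrt(3) beta f) = 39 cm
  ac <- autocorrelogram(m)
  cx <- (nrow(ac) + 1) / 2; cy <- (ncol(ac) + 1) / 2
  rr <- sqrt((row(ac) - cx)^2 + (col(ac) - cy)^2) * m$bin_x
  # search beyond the central peak's extent
  radii <- seq(18, 60, by = 3)
  ring <- sapply(radii, function(r) {
    mean(ac[rr >= r - 1.5 & rr < r + 1.5], na.rm = TRUE)
  })
  peak_r <- radii[which.max(ring)]
  expect_equal(peak_r, 2 / (sqrt(3) * p$beta * p$f), tolerance = 0.15)
})

test_that("compression scan recovers identity and an imposed 30 % compression", {
  env <- test_env()
  trajA <- test_traj(env, n = 15000, seed = 9)
  spikes_from <- function(traj, squeeze = 1) {
    val <- hex_pattern(traj$x, traj$y * squeeze, spacing = 35)
    tibble::tibble(t = traj$t, spike = as.integer(val > 0.75))
  }
  mA <- rate_map(spikes_from(trajA), trajA)
  scan0 <- compression_scan(mA, mA, axis = "y")
  expect_equal(attr(scan0, "argmax"), 0, tolerance = 1)
  # configuration-B trajectory whose firing pattern is the A pattern
  # compressed such that a 30 % stretch of the shift restores it
  trajB <- test_traj(env, n = 15000, seed = 10, config = "B")
  mB <- rate_map(spikes_from(trajB, squeeze = 1.15), trajB)
  scan30 <- compression_scan(mA, mB, axis = "y")
  expect_equal(attr(scan30, "argmax"), 30, tolerance = 3)
  gl <- glance(scan30)
  expect_equal(gl$argmax_percent, attr(scan30, "argmax"))
  expect_true(gl$r2_max > 0.5 && gl$r2_max <= 1)
})

test_that("scan direction is consistent: compressing A matches expanding B", {
  env <- test_env()
  trajA <- test_traj(env, n = 12000, seed = 11)
  trajB <- test_traj(env, n = 12000, seed = 12, config = "B")
  spikes_from <- function(traj, squeeze = 1) {
    val <- hex_pattern(traj$x, traj$y * squeeze, spacing = 35)
    tibble::tibble(t = traj$t, spike = as.integer(val > 0.75))
  }
  mA <- rate_map(spikes_from(trajA), trajA)
  mB <- rate_map(spikes_from(trajB, 1.5), trajB)   # fully compressed pattern
  scan <- compression_scan(mA, mB, axis = "y")
  expect_equal(attr(scan, "argmax"), 100, tolerance = 3)
})

test_that("gridness separates hexagonal, noise and square maps", {
  hex_map <- synthetic_map(function(x, y) hex_pattern(x, y, spacing = 40))
  expect_gt(gridness(hex_map), 0.8)
  sq <- synthetic_map(function(x, y) {
    (cos(2 * pi * x / 40) + cos(2 * pi * y / 40) + 2) / 4
  })
  expect_lt(gridness(sq), -0.2)
  set.seed(13)
  scores <- sapply(1:6, function(i) {
    m <- synthetic_map(function(x, y) 0 * x)
    m$rate <- matrix(runif(length(m$rate)), nrow(m$rate))
    gridness(m)
  })
  expect_lt(abs(mean(scores)), 0.35)
  flat <- synthetic_map(function(x, y) 0 * x + 1)
  expect_error(gridness(flat), "degenerate")
})

test_that("euclidean error is exact on identity and respects the diagonal bound", {
  traj <- test_traj(n = 2000, seed = 14)
  est <- tibble::tibble(t = traj$t, x_hat = traj$x, y_hat = traj$y)
  expect_true(all(euclidean_error(est, traj)$error == 0))
  # any in-box estimate stays under the diagonal
  est2 <- tibble::tibble(t = traj$t, x_hat = rev(traj$x), y_hat = rev(traj$y))
  expect_lte(max(euclidean_error(est2, traj)$error), sqrt(2) * 150)
  expect_error(euclidean_error(est2[-1, ], traj), "lengths differ")
})

test_that("error bands summarize trials with mean +/- 1 SD", {
  err <- rbind(rep(1, 5), rep(3, 5))
  b <- error_band(err, t = 1:5)
  expect_equal(b$mean, rep(2, 5))
  expect_equal(b$upper - b$lower, rep(2 * sd(c(1, 3)), 5))
})

test_that("autoplot methods return ggplot objects", {
  traj <- test_traj(n = 1000, seed = 15)
  expect_s3_class(autoplot(traj), "ggplot")
  sp <- vco_spikes(traj, vco_params())
  m <- rate_map(sp, traj)
  expect_s3_class(autoplot(m), "ggplot")
  env <- test_env()
  est <- estimate_path_moving(traj, env, "A")
  expect_s3_class(autoplot(est), "ggplot")
})
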