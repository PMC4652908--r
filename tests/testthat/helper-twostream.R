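# Shared fixtures, built in code. Environments and trajectories are cheap to
# regenerate, so helpers construct them on demand with fixed seeds.

test_env <- function(seed = 1) {
  build_environment(box_config("A"), seed = seed)
}

test_traj <- function(env = test_env(), n = 2000, seed = 2, config = "A") {
  synthesize_trajectory(env, movement_params(n_sample = n), seed = seed,
                        config = config)
}

# Random interior poses for property-style loops.
random_poses <- function(n, seed, box = 150, margin = 20) {
  set.seed(seed)
  tibble::tibble(
    x = stats::runif(n, margin, box - margin),
    y = stats::runif(n, margin, box - margin),
    phi = stats::runif(n, -pi, pi)
  )
}

# Analytic hexagonal pattern (three plane waves at 60 degrees) used to build
# synthetic rate maps with known spacing; returns values in [0, 1]-ish range.
hex_pattern <- function(x, y, spacing = 30, phase = c(0, 0)) {
  k <- 4 * pi / (sqrt(3) * spacing)
  dirs <- rbind(c(cos(pi / 6), sin(pi / 6)),
                c(cos(pi / 2), sin(pi / 2)),
                c(cos(5 * pi / 6), sin(5 * pi / 6)))
  v <- 0
  for (i in 1:3) {
    v <- v + cos(k * ((x - phase[1]) * dirs[i, 1] + (y - phase[2]) * dirs[i, 2]))
  }
  (v + 3) / 6
}

# Rate-map object wrapped around an analytic field evaluated on a grid.
synthetic_map <- function(f, extent = c(150, 150), bin = 3) {
  xb <- seq(0, extent[1], length.out = round(extent[1] / bin) + 1)
  yb <- seq(0, extent[2], length.out = round(extent[2] / bin) + 1)
  xc <- (xb[-1] + xb[-length(xb)]) / 2
  yc <- (yb[-1] + yb[-length(yb)]) / 2
  rate <- outer(xc, yc, f)
  structure(list(rate = rate, x_breaks = xb, y_breaks = yb, bin = bin,
                 bin_x = diff(xb[1:2]), bin_y = diff(yb[1:2]), smooth = 0),
            class = "rate_map")
}

# Build a wall-observation table for a rat at (xs, ys) in a box whose north
# wall sits at cy * 150 and east wall at cx * 150, while the memorized
# positions stay at the uncompressed 150 x 150 layout (mirroring a barrier
# shift). Features on the moved walls ride along; features on the fixed
# walls beyond the new planes are dropped, as the occlusion rule dictates.
compressed_scene <- function(xs, ys, cy = 1, cx = 1, seed = 1,
                             env = test_env(seed = seed)) {
  mem <- env_features(env, "A")
  mem <- mem[mem$surface %in% c("N-wall", "S-wall", "W-wall", "E-wall"), ]
  act_x <- ifelse(mem$surface == "E-wall", cx * mem$x, mem$x)
  act_y <- ifelse(mem$surface == "N-wall", cy * mem$y, mem$y)
  keep <- act_x <= cx * 150 + 1e-9 & act_y <= cy * 150 + 1e-9
  tibble::tibble(
    wall = substr(mem$surface[keep], 1, 1),
    bearing = atan2(act_y[keep] - ys, act_x[keep] - xs),
    x = mem$x[keep], y = mem$y[keep]
  )
}

# Independent oracle: minimize the full functional numerically with every
# per-feature range lambda kept as a free parameter.
minimize_functional <- function(walls, L = 150, W = 150, alpha = 1e-4,
                                start = NULL) {
  ns <- walls$wall %in% c("N", "S")
  iN <- walls$wall == "N"; iS <- walls$wall == "S"
  iW <- walls$wall == "W"; iE <- walls$wall == "E"
  psi <- walls$bearing
  m <- nrow(walls)
  E_fun <- function(p) {
    xs <- p[1]; ys <- p[2]; eta <- p[3]; xi <- p[4]
    lam <- p[-(1:4)]
    adj_x <- ifelse(ns, walls$x, eta * walls$x)
    adj_y <- ifelse(ns, xi * walls$y, walls$y)
    tri <- (xs - adj_x - lam * cos(psi))^2 + (ys - adj_y - lam * sin(psi))^2
    e <- sum((1 - alpha) / sum(ns) * tri[ns]) +
      sum((1 - alpha) / sum(!ns) * tri[!ns])
    tn <- tan(psi[iN]); ts <- tan(psi[iS])
    cw <- 1 / tan(psi[iW]); ce <- 1 / tan(psi[iE])
    prs <- expand.grid(k = seq_len(sum(iN)), l = seq_len(sum(iS)))
    rho_ns <- (walls$x[iN][prs$k] - xs) * tn[prs$k] -
      (walls$x[iS][prs$l] - xs) * ts[prs$l] - xi * L
    prw <- expand.grid(mu = seq_len(sum(iW)), nu = seq_len(sum(iE)))
    rho_we <- (walls$y[iE][prw$nu] - ys) * ce[prw$nu] -
      (walls$y[iW][prw$mu] - ys) * cw[prw$mu] - eta * W
    e + alpha / nrow(prs) * sum(rho_ns^2) + alpha / nrow(prw) * sum(rho_we^2)
  }
  if (is.null(start)) start <- c(75, 75, 1, 1, rep(80, m))
  opt <- optim(start, E_fun, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  list(par = opt$par[1:4], value = opt$value, E = E_fun)
}

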