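#' Parameters of the velocity controlled oscillator (VCO) grid model
#'
#' Oscillatory-interference grid model: three oscillations whose phases are
#' driven by the location signal projected onto basis vectors at 0, 120 and
#' 240 degrees interfere with a baseline theta oscillation; the cell spikes
#' whenever the product of the three interference pairs exceeds a threshold.
#' The grid spacing scales as `2 / (sqrt(3) * beta * f)` (about 39 cm for
#' the default `beta = 0.004`, and larger for smaller `beta`), with band
#' spacing `1 / (beta * f)` along each basis direction; both are verified
#' empirically from simulated rate maps in the test-suite rather than
#' asserted.
#'
#' @param f Theta-rhythm frequency (Hz).
#' @param beta Grid-spacing parameter (dimensionless); 0.004 models a dorsal
#'   (narrow-spacing) cell driven by the moving feature system, 0.003 a
#'   ventral (wide-spacing) cell driven by the static feature system.
#' @param threshold Spike threshold on the three-fold product.
#' @return An object of class `vco_params`.
#' @export
vco_params <- function(f = 7.38, beta = 0.004, threshold = 1.8) {
  stopifnot(f > 0, beta > 0)
  structure(list(f = f, beta = beta, threshold = threshold,
                 basis = rbind(c(cos(0), sin(0)),
                               c(cos(2 * pi / 3), sin(2 * pi / 3)),
                               c(cos(4 * pi / 3), sin(4 * pi / 3)))),
            class = "vco_params")
}

#' @export
print.vco_params <- function(x, ...) {
  cat(sprintf("<vco_params: f = %g Hz, beta = %g, threshold = %g>\n",
              x$f, x$beta, x$threshold))
  invisible(x)
}

#' Grid-cell spike train from the oscillatory-interference model
#'
#' Evaluates, at every sample time `t_j` with location `x_j` (cm), the
#' interference product
#' \deqn{\prod_{k=1}^{3}\big[\cos(\omega t_j) +
#'   \cos(\omega t_j + \omega\beta\, \vec x_j\cdot\vec b_k)\big]}
#' with `omega = 2 pi f`, and emits a spike where it exceeds the threshold.
#' The location signal is consumed directly (not a velocity signal); any
#' location estimate series or trajectory works as input. Translating all
#' locations by one grid period leaves the spike pattern unchanged.
#'
#' @param loc Data frame with columns `t` (s) and either `x_hat`/`y_hat`
#'   (a location estimate series) or `x`/`y` (a trajectory).
#' @param params A [vco_params()].
#' @return Tibble with columns `t` and `spike` (0/1), one row per input row.
#' @examples
#' loc <- data.frame(t = seq(0, 5, by = 0.05), x = 0, y = 0)
#' mean(vco_spikes(loc, vco_params())$spike)  # fires near theta peaks
#' @export
vco_spikes <- function(loc, params = vco_params()) {
  stopifnot(inherits(params, "vco_params"), "t" %in% names(loc))
  xs <- if ("x_hat" %in% names(loc)) loc$x_hat else loc$x
  ys <- if ("y_hat" %in% names(loc)) loc$y_hat else loc$y
  if (is.null(xs) || is.null(ys)) {
    stop("loc needs x_hat/y_hat or x/y columns", call. = FALSE)
  }
  if (any(!is.finite(xs) | !is.finite(ys))) {
    stop("non-finite locations in VCO input", call. = FALSE)
  }
  omega <- 2 * pi * params$f
  base <- cos(omega * loc$t)
  prod3 <- rep(1, nrow(loc))
  for (k in 1:3) {
    proj <- xs * params$basis[k, 1] + ys * params$basis[k, 2]
    prod3 <- prod3 * (base + cos(omega * loc$t + omega * params$beta * proj))
  }
  tibble::tibble(t = loc$t, spike = as.integer(prod3 > params$threshold))
}

#' Parameters of the twisted-torus attractor grid model
#'
#' Recurrent network of `n_x * n_y` cells arranged on a twisted torus whose
#' activity bump array is shifted by a velocity input; the half-row twist in
#' the boundary wrap-around makes the resulting spatial firing hexagonal
#' rather than square. Grid spacing is set by the input gain: a bump crosses
#' one torus period when the rat covers roughly `1 / (f_sample * alpha)` cm,
#' so smaller gains give wider grids.
#'
#' @param n_x,n_y Sheet dimensions (cells).
#' @param I Peak synaptic strength.
#' @param T_inhib Inhibition offset subtracted from all weights.
#' @param alpha Velocity input gain (torus units per cm/s per update);
#'   1.4e-3 models the dorsal cell, 0.9e-3 the ventral cell.
#' @param sigma Gaussian footprint of the synaptic profile (torus units).
#' @param gamma Grid orientation (degrees); rotates the velocity input.
#' @param tau History weight of the exponentially weighted activity average.
#' @param eta Spike threshold on the readout cell's activity.
#' @return An object of class `attractor_params` with the readout cell index
#'   `n_x * n_y - n_y / 2` precomputed.
#' @export
attractor_params <- function(n_x = 9, n_y = 10, I = 0.3, T_inhib = 0.05,
                             alpha = 1.4e-3, sigma = 0.24, gamma = 0,
                             tau = 0.8, eta = 0.1) {
  stopifnot(n_x >= 2, n_y >= 2, I > 0, sigma > 0, tau >= 0, tau <= 1)
  structure(list(n_x = n_x, n_y = n_y, I = I, T_inhib = T_inhib,
                 alpha = alpha, sigma = sigma, gamma = gamma, tau = tau,
                 eta = eta, readout = n_x * n_y - round(n_y / 2)),
            class = "attractor_params")
}

#' @export
print.attractor_params <- function(x, ...) {
  cat(sprintf(
    "<attractor_params: %d x %d cells, I = %g, T = %g, alpha = %g, sigma = %g, readout #%d>\n",
    x$n_x, x$n_y, x$I, x$T_inhib, x$alpha, x$sigma, x$readout))
  invisible(x)
}

# Cell coordinates on the twisted torus (unit square, y scaled by sqrt(3)/2)
# and the seven wrap-around copies implementing the half-row twist.
torus_geometry <- function(p) {
  i <- rep(seq_len(p$n_x), each = p$n_y)
  j <- rep(seq_len(p$n_y), times = p$n_x)
  cells <- cbind(x = (i - 0.5) / p$n_x,
                 y = sqrt(3) / 2 * (j - 0.5) / p$n_y)
  shifts <- rbind(c(0, 0),
                  c(-1, 0), c(1, 0),
                  c(-0.5, sqrt(3) / 2), c(0.5, sqrt(3) / 2),
                  c(-0.5, -sqrt(3) / 2), c(0.5, -sqrt(3) / 2))
  list(cells = cells, shifts = shifts)
}

# Squared twisted-torus distance between all cell pairs after adding the 2D
# offset (ox, oy): minimum over the seven torus copies.
torus_dist2 <- function(dx, dy, ox, oy, shifts) {
  qx <- dx + ox
  qy <- dy + oy
  d2 <- (qx + shifts[1, 1])^2 + (qy + shifts[1, 2])^2
  for (s in 2:nrow(shifts)) {
    d2 <- pmin(d2, (qx + shifts[s, 1])^2 + (qy + shifts[s, 2])^2)
  }
  d2
}

#' Grid-cell spike train from the twisted-torus attractor model
#'
#' Integrates the attractor network along a 2D velocity signal: at every
#' step the synaptic weight matrix is the Gaussian of the twisted-torus
#' distance between cells, shifted by the gain-scaled, orientation-rotated
#' velocity and lowered by the inhibition offset; activities are updated by
#' the weight matrix, mixed with the previous activation (history weight
#' `tau`), normalized by the summed activity and half-wave rectified. The
#' readout cell spikes whenever its activity exceeds `eta`. For the static
#' feature system, use the temporal difference of the location estimates as
#' the velocity signal (see [location_velocity()]).
#'
#' @param vel Data frame with columns `t` (s), `vx`, `vy` (cm/s), one row
#'   per update step.
#' @param params An [attractor_params()].
#' @param seed Seed for the random uniform initialization of the activities.
#' @param burn_in Number of zero-velocity warm-up updates run before the
#'   velocity signal starts, letting the bump array form.
#' @return Tibble with columns `t` and `spike` (0/1), one row per input row.
#'   The final activity vector is attached as attribute `activity`.
#' @export
attractor_spikes <- function(vel, params = attractor_params(), seed = 1,
                             burn_in = 100) {
  stopifnot(inherits(params, "attractor_params"),
            all(c("t", "vx", "vy") %in% names(vel)))
  if (any(!is.finite(vel$vx) | !is.finite(vel$vy))) {
    stop("non-finite velocities in attractor input", call. = FALSE)
  }
  geo <- torus_geometry(params)
  ncell <- nrow(geo$cells)
  dx <- outer(geo$cells[, 1], geo$cells[, 1], "-")
  dy <- outer(geo$cells[, 2], geo$cells[, 2], "-")
  g <- params$gamma * pi / 180
  rot <- matrix(c(cos(g), sin(g), -sin(g), cos(g)), 2, 2)

  if (!is.null(seed)) set.seed(seed)
  a <- stats::runif(ncell, 0, 1 / sqrt(ncell))
  b_prev <- a

  # Activity update: b(t+1) = W a(t), then mix the new drive with the
  # previous one normalized by the summed activity and half-wave rectify.
  # Normalizing only the history term (the printed form) is the stable
  # reading; dividing the whole mixture by sum(a) sets off a growing
  # two-cycle and is not used.
  step <- function(vx, vy, a, b_prev) {
    sh <- params$alpha * (rot %*% c(vx, vy))
    d2 <- torus_dist2(dx, dy, sh[1], sh[2], geo$shifts)
    W <- params$I * exp(-d2 / params$sigma^2) - params$T_inhib
    b <- drop(W %*% a)
    mix <- (1 - params$tau) * b + params$tau * b_prev / sum(a)
    list(a = pmax(mix, 0), b = b)
  }

  for (k in seq_len(burn_in)) {
    st <- step(0, 0, a, b_prev)
    a <- st$a; b_prev <- st$b
  }
  n <- nrow(vel)
  spikes <- integer(n)
  ro <- params$readout
  for (j in seq_len(n)) {
    st <- step(vel$vx[j], vel$vy[j], a, b_prev)
    a <- st$a; b_prev <- st$b
    spikes[j] <- as.integer(a[ro] > params$eta)
  }
  out <- tibble::tibble(t = vel$t, spike = spikes)
  attr(out, "activity") <- a
  out
}

#' Velocity signal from a location series
#'
#' Temporal difference of sequential locations, the velocity input required
#' by the attractor model when driven by the static feature system's
#' location estimates.
#'
#' @param loc Data frame with columns `t` and `x_hat`/`y_hat` (or `x`/`y`).
#' @return Tibble with columns `t`, `vx`, `vy` (cm/s), one row per step
#'   (one fewer than `loc`), timestamped at the step's end.
#' @export
location_velocity <- function(loc) {
  xs <- if ("x_hat" %in% names(loc)) loc$x_hat else loc$x
  ys <- if ("y_hat" %in% names(loc)) loc$y_hat else loc$y
  dt <- diff(loc$t)
  tibble::tibble(t = loc$t[-1], vx = diff(xs) / dt, vy = diff(ys) / dt)
}
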