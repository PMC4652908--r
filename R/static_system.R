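#' Transform wall-landmark azimuths to the per-wall triangulation convention
#'
#' The triangulation geometry references each wall's landmarks through a
#' wall-specific angle: with `psi` the allocentric bearing of a landmark
#' (egocentric azimuth plus heading), the transformed angles are
#' `theta_k = psi` (north wall), `theta_l = -psi` (south),
#' `theta_mu = psi - pi/2` (west) and `theta_nu = -psi - pi/2` (east).
#'
#' @param obs Data frame of wall observations with columns `surface` (one of
#'   `"N-wall"`, `"S-wall"`, `"W-wall"`, `"E-wall"`) and `azimuth`
#'   (egocentric, radians); further columns are carried through.
#' @param heading Heading used to re-reference the egocentric azimuths to
#'   the allocentric frame (radians); for a rat that starts at heading
#'   `phi0` and whose turns are tracked, this is the current head direction.
#' @return `obs` with columns `wall` (`"N"`, `"S"`, `"W"`, `"E"`), `bearing`
#'   (allocentric, radians) and `theta` (transformed angle, radians)
#'   appended.
#' @examples
#' obs <- data.frame(surface = c("N-wall", "S-wall", "W-wall"),
#'                   azimuth = c(0.3, 0.3, pi / 2))
#' transform_wall_angles(obs)$theta  # 0.3, -0.3, 0
#' @export
transform_wall_angles <- function(obs, heading = 0) {
  stopifnot(all(c("surface", "azimuth") %in% names(obs)))
  if (!all(obs$surface %in% c("N-wall", "S-wall", "W-wall", "E-wall"))) {
    stop("transform_wall_angles() expects wall features only", call. = FALSE)
  }
  obs <- tibble::as_tibble(obs)
  psi <- wrap_angle(obs$azimuth + heading)
  wall <- substr(obs$surface, 1, 1)
  dplyr::mutate(
    obs,
    wall = wall,
    bearing = psi,
    theta = wrap_angle(dplyr::case_when(
      wall == "N" ~ psi,
      wall == "S" ~ -psi,
      wall == "W" ~ psi - pi / 2,
      wall == "E" ~ -psi - pi / 2
    ))
  )
}

# Transformed per-wall angle back to the allocentric bearing.
theta_to_bearing <- function(theta, wall) {
  wrap_angle(ifelse(wall == "N", theta,
             ifelse(wall == "S", -theta,
             ifelse(wall == "W", theta + pi / 2, -theta - pi / 2))))
}

#' Regularized triangulation of location from wall landmarks
#'
#' Estimates the rat's planar location together with two compression factors
#' from the bearings of landmarks on the four walls and their memorized
#' positions in the remembered (uncompressed) box. Two families of squared
#' residuals are combined into the functional that is minimized:
#'
#' * *Triangulation terms* (weight `1 - alpha`, averaged per wall pairing):
#'   the ray from the estimated location toward the compression-adjusted
#'   memorized landmark -- `(x_i, xi * y_i)` for north/south landmarks,
#'   `(eta * x_i, y_i)` for west/east -- must point along the observed
#'   bearing. Eliminating each unknown range `lambda_i` (it enters its two
#'   residuals quadratically, so its stationarity condition is linear)
#'   reduces every landmark to the perpendicular deviation of the adjusted
#'   memorized point from the observed ray, which is linear in
#'   `(x_s, y_s, eta, xi)`.
#' * *Box-dimension terms* (weight `alpha`, averaged over all pairs of
#'   landmarks on opposite walls): stacking the two right triangles that an
#'   opposite-wall landmark pair forms with the rat forces the apparent
#'   north-south extent to equal `xi * L` and the west-east extent
#'   `eta * W`, where `L` and `W` are the memorized box length and width.
#'
#' The combined least-squares problem is linear, and the minimizer solves a
#' symmetric 4x4 normal-equation system in closed form (verified in the
#' test-suite against direct numerical minimization of the functional with
#' all ranges kept as free parameters). The location estimate is finally
#' rescaled by the compression factors, `x = x_s / eta`, `y = y_s / xi`,
#' which maps positions in a compressed box back onto the remembered
#' coordinates -- the mechanism by which the static system "fills" the
#' remembered box after a barrier shift.
#'
#' @param walls Data frame with one row per observed wall landmark: columns
#'   `wall` (`"N"`, `"S"`, `"W"`, `"E"`), `theta` (transformed angle from
#'   [transform_wall_angles()]) **or** `bearing` (allocentric bearing,
#'   radians), and memorized positions `x`, `y` (cm, remembered-box frame).
#' @param L Memorized box length in y (cm).
#' @param W Memorized box width in x (cm).
#' @param alpha Regularization weight in (0, 1) balancing triangulation
#'   against the box-dimension constraint.
#' @return One-row tibble with `x_s_hat`, `y_s_hat` (pre-rescaling, cm),
#'   `eta_hat`, `xi_hat` (compression factors), and the rescaled location
#'   `x_hat`, `y_hat` (cm). The signed ranges `lambda` along each observed
#'   ray are attached as an attribute.
#' @examples
#' env <- build_environment(box_config("A"), seed = 1)
#' obs <- available_features(env, x = 60, y = 90, phi = 0)
#' w <- transform_wall_angles(dplyr::filter(obs, group == "wall"))
#' mem <- env_features(env, "A")
#' w <- dplyr::left_join(w, mem[, c("id", "x", "y")], by = "id")
#' triangulate(w)  # recovers (60, 90) with eta = xi = 1
#' @export
triangulate <- function(walls, L = 150, W = 150, alpha = 1e-4) {
  stopifnot(is.data.frame(walls), alpha > 0, alpha < 1, L > 0, W > 0)
  need <- c("wall", "x", "y")
  if (!all(need %in% names(walls))) {
    stop("`walls` needs columns wall, x, y and theta or bearing",
         call. = FALSE)
  }
  if (!all(c("N", "S", "W", "E") %in% walls$wall)) {
    stop("triangulation needs at least one landmark on each of the four walls",
         call. = FALSE)
  }
  psi <- if ("bearing" %in% names(walls)) {
    walls$bearing
  } else {
    theta_to_bearing(walls$theta, walls$wall)
  }

  s <- sin(psi)
  c_ <- cos(psi)
  ns <- walls$wall %in% c("N", "S")
  we <- !ns
  n_ns <- sum(ns)
  n_we <- sum(we)
  iN <- walls$wall == "N"; iS <- walls$wall == "S"
  iW <- walls$wall == "W"; iE <- walls$wall == "E"

  # rows of the linear residual system r = A p - b, p = (x_s, y_s, eta, xi)
  A <- matrix(0, nrow(walls) , 4)
  b <- numeric(nrow(walls))
  A[ns, 1] <- -s[ns]; A[ns, 2] <- c_[ns]; A[ns, 4] <- -c_[ns] * walls$y[ns]
  b[ns] <- -s[ns] * walls$x[ns]
  A[we, 1] <- -s[we]; A[we, 2] <- c_[we]; A[we, 3] <- s[we] * walls$x[we]
  b[we] <- c_[we] * walls$y[we]
  wts <- ifelse(ns, (1 - alpha) / n_ns, (1 - alpha) / n_we)

  # opposite-wall pair rows
  Tn <- tan(psi[iN]); Ts <- tan(psi[iS])
  Cw <- 1 / tan(psi[iW]); Ce <- 1 / tan(psi[iE])
  pr_ns <- expand.grid(k = seq_len(sum(iN)), l = seq_len(sum(iS)))
  pr_we <- expand.grid(m = seq_len(sum(iW)), v = seq_len(sum(iE)))
  xN <- walls$x[iN]; xS <- walls$x[iS]
  yW <- walls$y[iW]; yE <- walls$y[iE]
  A_ns <- cbind(Ts[pr_ns$l] - Tn[pr_ns$k], 0, 0, -L)
  b_ns <- xS[pr_ns$l] * Ts[pr_ns$l] - xN[pr_ns$k] * Tn[pr_ns$k]
  A_we <- cbind(0, Cw[pr_we$m] - Ce[pr_we$v], -W, 0)
  b_we <- yW[pr_we$m] * Cw[pr_we$m] - yE[pr_we$v] * Ce[pr_we$v]

  A <- rbind(A, A_ns, A_we)
  b <- c(b, b_ns, b_we)
  wts <- c(wts, rep(alpha / nrow(pr_ns), nrow(pr_ns)),
           rep(alpha / nrow(pr_we), nrow(pr_we)))

  M <- crossprod(A * wts, A)
  d <- crossprod(A * wts, b)
  p <- tryCatch(drop(solve(M, d)),
                error = function(e) stop("singular triangulation geometry: ",
                                         conditionMessage(e), call. = FALSE))

  adj_x <- ifelse(we, p[3] * walls$x, walls$x)
  adj_y <- ifelse(ns, p[4] * walls$y, walls$y)
  # stationarity value of each range parameter (projection of the offset on
  # the observed ray); its magnitude is the eye-to-landmark range
  lambda <- (p[1] - adj_x) * c_ + (p[2] - adj_y) * s
  out <- tibble::tibble(
    x_s_hat = p[1], y_s_hat = p[2], eta_hat = p[3], xi_hat = p[4],
    x_hat = p[1] / p[3], y_hat = p[2] / p[4]
  )
  attr(out, "lambda") <- lambda
  out
}

#' Location estimate of the static feature system along a trajectory
#'
#' Runs the regularized triangulation of [triangulate()] independently at
#' every sample of a trajectory: observe the bearings of the visible wall
#' landmarks, optionally superimpose Gaussian noise in the angle domain
#' (see [noise_spec()]), solve the 4x4 system for location and compression
#' factors, and rescale. Estimates are frame-by-frame -- perturbing one
#' observation changes only that sample's estimate, so errors never
#' accumulate (the defining contrast with [estimate_path_moving()]). When
#' the box has been compressed relative to the memorized configuration-A
#' layout, the compression factors absorb the conflict between sensed
#' bearings and memorized geometry and the rescaled estimates fill the
#' remembered box.
#'
#' @param traj A [synthesize_trajectory()] result.
#' @param env The [build_environment()] the trajectory lives in.
#' @param config "A" or "B": box configuration being observed. Memorized
#'   landmark positions and box dimensions always come from configuration A.
#' @param noise `NULL` (noise-free) or a [noise_spec()] with domain
#'   `"angle"`; noise is drawn independently for every landmark and sample
#'   (azimuth and elevation both perturbed; the triangulation consumes the
#'   azimuths).
#' @param seed Seed for the noise draws.
#' @param alpha Regularization weight, see [triangulate()].
#' @return Tibble of class `ts_location_estimate`, aligned row-for-row with
#'   `traj`: columns `t`, `x_hat`, `y_hat` (rescaled, cm), `eta_hat`,
#'   `xi_hat`, and `source = "static"`.
#' @export
estimate_path_static <- function(traj, env, config = c("A", "B"),
                                 noise = NULL, seed = NULL, alpha = 1e-4) {
  stopifnot(inherits(env, "box_environment"))
  config <- match.arg(config)
  wa <- wall_angle_matrices(traj, env, config)
  psi <- wa$bearing
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (noise$domain != "angle") {
      stop("static-system noise must live in the angle domain", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    psi <- psi + matrix(stats::rnorm(length(psi), noise$mean * pi / 180,
                                     noise$sd * pi / 180), nrow(psi))
  }
  mem_box <- env_config(env, "A")
  sol <- triangulate_batch(psi, wa$mask, wa$surface, wa$mem_x, wa$mem_y,
                           L = mem_box$length_y, W = mem_box$width_x,
                           alpha = alpha)
  out <- tibble::tibble(
    t = traj$t,
    x_hat = sol$x / sol$eta,
    y_hat = sol$y / sol$xi,
    eta_hat = sol$eta,
    xi_hat = sol$xi,
    source = "static"
  )
  class(out) <- c("ts_location_estimate", class(out))
  out
}

# Vectorized triangulation over all samples at once. psi and mask are
# n x m matrices of allocentric bearings / visibility for the m wall
# landmarks; all opposite-wall pair sums collapse onto per-wall sums, and the
# 4x4 normal equations are solved by a vectorized Cholesky factorization.
triangulate_batch <- function(psi, mask, surface, mem_x, mem_y, L, W, alpha) {
  n <- nrow(psi)
  s <- sin(psi); c_ <- cos(psi)

  d1 <- d2 <- d3 <- d4 <- numeric(n)
  m11 <- m12 <- m13 <- m14 <- m22 <- m23 <- m24 <- m33 <- m44 <- numeric(n)

  idx <- list(N = surface == "N-wall", S = surface == "S-wall",
              W = surface == "W-wall", E = surface == "E-wall")
  cnt <- lapply(idx, function(i) rowSums(mask[, i, drop = FALSE]))
  n_ns <- cnt$N + cnt$S
  n_we <- cnt$W + cnt$E
  if (any(cnt$N < 1 | cnt$S < 1 | cnt$W < 1 | cnt$E < 1)) {
    stop("some samples see no landmark on one of the four walls; ",
         "triangulation undefined", call. = FALSE)
  }

  # triangulation terms, north/south walls
  for (wl in c("N", "S")) {
    i <- idx[[wl]]
    w <- mask[, i, drop = FALSE] * (1 - alpha) / n_ns
    si <- s[, i, drop = FALSE]; ci <- c_[, i, drop = FALSE]
    xi_ <- matrix(mem_x[i], n, sum(i), byrow = TRUE)
    yi_ <- matrix(mem_y[i], n, sum(i), byrow = TRUE)
    m11 <- m11 + rowSums(w * si^2)
    m12 <- m12 - rowSums(w * si * ci)
    m14 <- m14 + rowSums(w * si * ci * yi_)
    m22 <- m22 + rowSums(w * ci^2)
    m24 <- m24 - rowSums(w * ci^2 * yi_)
    m44 <- m44 + rowSums(w * ci^2 * yi_^2)
    d1 <- d1 + rowSums(w * si^2 * xi_)
    d2 <- d2 - rowSums(w * si * ci * xi_)
    d4 <- d4 + rowSums(w * si * ci * xi_ * yi_)
  }
  # triangulation terms, west/east walls
  for (wl in c("W", "E")) {
    i <- idx[[wl]]
    w <- mask[, i, drop = FALSE] * (1 - alpha) / n_we
    si <- s[, i, drop = FALSE]; ci <- c_[, i, drop = FALSE]
    xi_ <- matrix(mem_x[i], n, sum(i), byrow = TRUE)
    yi_ <- matrix(mem_y[i], n, sum(i), byrow = TRUE)
    m11 <- m11 + rowSums(w * si^2)
    m12 <- m12 - rowSums(w * si * ci)
    m13 <- m13 - rowSums(w * si^2 * xi_)
    m22 <- m22 + rowSums(w * ci^2)
    m23 <- m23 + rowSums(w * si * ci * xi_)
    m33 <- m33 + rowSums(w * si^2 * xi_^2)
    d1 <- d1 - rowSums(w * si * ci * yi_)
    d2 <- d2 + rowSums(w * ci^2 * yi_)
    d3 <- d3 + rowSums(w * si * ci * xi_ * yi_)
  }

  # opposite-wall pair terms, expanded into per-wall sums
  Tm <- tan(psi)
  Cm <- 1 / Tm
  wallsums <- function(val, i) {
    mk <- mask[, i, drop = FALSE]
    vv <- val[, i, drop = FALSE]
    xm <- matrix(mem_x[i], n, sum(i), byrow = TRUE)
    ym <- matrix(mem_y[i], n, sum(i), byrow = TRUE)
    list(P1 = rowSums(mk * vv), P2 = rowSums(mk * vv^2),
         Qx1 = rowSums(mk * xm * vv), Qx2 = rowSums(mk * xm * vv^2),
         Qy1 = rowSums(mk * ym * vv), Qy2 = rowSums(mk * ym * vv^2))
  }
  SN <- wallsums(Tm, idx$N); SS <- wallsums(Tm, idx$S)
  SW <- wallsums(Cm, idx$W); SE <- wallsums(Cm, idx$E)

  w3 <- alpha / (cnt$N * cnt$S)
  m11 <- m11 + w3 * (cnt$N * SS$P2 + cnt$S * SN$P2 - 2 * SN$P1 * SS$P1)
  m14 <- m14 - w3 * L * (cnt$N * SS$P1 - cnt$S * SN$P1)
  m44 <- m44 + w3 * L^2 * cnt$N * cnt$S
  d1 <- d1 + w3 * (cnt$N * SS$Qx2 - SS$P1 * SN$Qx1 - SN$P1 * SS$Qx1 +
                     cnt$S * SN$Qx2)
  d4 <- d4 - w3 * L * (cnt$N * SS$Qx1 - cnt$S * SN$Qx1)

  w4 <- alpha / (cnt$W * cnt$E)
  m22 <- m22 + w4 * (cnt$W * SE$P2 + cnt$E * SW$P2 - 2 * SW$P1 * SE$P1)
  m23 <- m23 - w4 * W * (cnt$E * SW$P1 - cnt$W * SE$P1)
  m33 <- m33 + w4 * W^2 * cnt$W * cnt$E
  d2 <- d2 + w4 * (cnt$E * SW$Qy2 - SE$P1 * SW$Qy1 - SW$P1 * SE$Qy1 +
                     cnt$W * SE$Qy2)
  d3 <- d3 - w4 * W * (cnt$E * SW$Qy1 - cnt$W * SE$Qy1)

  sol <- chol4_solve(m11, m12, m13, m14, m22, m23, m24, m33, 0, m44,
                     d1, d2, d3, d4)
  bad <- which(!is.finite(sol$p1) | !is.finite(sol$p2) |
                 !is.finite(sol$p3) | !is.finite(sol$p4))
  for (j in bad) {  # rare fallback: exact solve per offending sample
    Mj <- matrix(c(m11[j], m12[j], m13[j], m14[j],
                   m12[j], m22[j], m23[j], m24[j],
                   m13[j], m23[j], m33[j], 0,
                   m14[j], m24[j], 0, m44[j]), 4, 4)
    pj <- tryCatch(solve(Mj, c(d1[j], d2[j], d3[j], d4[j])),
                   error = function(e) stop("singular triangulation at sample ",
                                            j, call. = FALSE))
    sol$p1[j] <- pj[1]; sol$p2[j] <- pj[2]; sol$p3[j] <- pj[3]; sol$p4[j] <- pj[4]
  }
  list(x = sol$p1, y = sol$p2, eta = sol$p3, xi = sol$p4)
}

# Vectorized Cholesky solve of many symmetric positive-definite 4x4 systems
# (one per element of the input vectors); m34 passed explicitly for clarity.
chol4_solve <- function(m11, m12, m13, m14, m22, m23, m24, m33, m34, m44,
                        d1, d2, d3, d4) {
  l11 <- sqrt(m11)
  l21 <- m12 / l11; l31 <- m13 / l11; l41 <- m14 / l11
  l22 <- sqrt(m22 - l21^2)
  l32 <- (m23 - l31 * l21) / l22
  l42 <- (m24 - l41 * l21) / l22
  l33 <- sqrt(m33 - l31^2 - l32^2)
  l43 <- (m34 - l41 * l31 - l42 * l32) / l33
  l44 <- sqrt(m44 - l41^2 - l42^2 - l43^2)
  z1 <- d1 / l11
  z2 <- (d2 - l21 * z1) / l22
  z3 <- (d3 - l31 * z1 - l32 * z2) / l33
  z4 <- (d4 - l41 * z1 - l42 * z2 - l43 * z3) / l44
  p4 <- z4 / l44
  p3 <- (z3 - l43 * p4) / l33
  p2 <- (z2 - l32 * p3 - l42 * p4) / l22
  p1 <- (z1 - l21 * p2 - l31 * p3 - l41 * p4) / l11
  list(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}
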