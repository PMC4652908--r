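#' Occupancy-normalized spatial firing-rate map
#'
#' Bins the trajectory into square spatial bins, accumulates occupancy time
#' and spike counts, smooths both with a Gaussian kernel and divides. The
#' map is always binned on the *true* positions; when the spike train was
#' generated from estimated locations, systematic estimation errors (such
#' as the static system's compression rescaling) appear as deformations of
#' the firing pattern in real space -- exactly what the compression scan
#' quantifies. Bins whose raw occupancy falls below `occupancy_min` are
#' masked.
#'
#' @param spikes Tibble from [vco_spikes()] or [attractor_spikes()] with
#'   columns `t` and `spike`.
#' @param traj The trajectory supplying the true positions (columns `t`,
#'   `x`, `y`); rows are matched to the spike train by time stamp.
#' @param bin Bin side length (cm).
#' @param smooth Gaussian smoothing width, standard deviation in cm; 0
#'   disables smoothing.
#' @param occupancy_min Minimum raw occupancy per bin (s) below which the
#'   bin is masked as unvisited.
#' @param extent Optional `c(width_x, length_y)` of the arena; defaults to
#'   the trajectory's box.
#' @return An object of class `rate_map`: list with `rate` (matrix, x bins
#'   by y bins, Hz; `NA` where masked), `x_breaks`, `y_breaks`, `bin`,
#'   `smooth`.
#' @export
rate_map <- function(spikes, traj, bin = 3, smooth = 3, occupancy_min = 0.1,
                     extent = NULL) {
  stopifnot(all(c("t", "spike") %in% names(spikes)),
            all(c("t", "x", "y") %in% names(traj)))
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  idx <- match(round(spikes$t, 9), round(traj$t, 9))
  if (any(is.na(idx))) {
    stop("spike train and trajectory time stamps do not align", call. = FALSE)
  }
  xs <- traj$x[idx]
  ys <- traj$y[idx]
  dt <- if (nrow(traj) > 1) traj$t[2] - traj$t[1] else 1
  if (is.null(extent)) {
    box <- attr(traj, "config")
    extent <- if (!is.null(box)) c(box$width_x, box$length_y) else
      c(max(xs), max(ys))
  }
  # uniform bins as close to the nominal size as the extent allows
  x_breaks <- seq(0, extent[1], length.out = max(2, round(extent[1] / bin) + 1))
  y_breaks <- seq(0, extent[2], length.out = max(2, round(extent[2] / bin) + 1))
  ix <- findInterval(xs, x_breaks, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(ys, y_breaks, rightmost.closed = TRUE, all.inside = TRUE)
  nx <- length(x_breaks) - 1
  ny <- length(y_breaks) - 1
  occ <- matrix(0, nx, ny)
  spk <- matrix(0, nx, ny)
  for (j in seq_along(ix)) {
    occ[ix[j], iy[j]] <- occ[ix[j], iy[j]] + dt
    spk[ix[j], iy[j]] <- spk[ix[j], iy[j]] + spikes$spike[j]
  }
  mask <- occ < occupancy_min
  if (smooth > 0) {
    occ_s <- gauss_smooth(occ, smooth / bin)
    spk_s <- gauss_smooth(spk, smooth / bin)
  } else {
    occ_s <- occ
    spk_s <- spk
  }
  rate <- spk_s / occ_s
  rate[mask | occ_s == 0] <- NA_real_
  structure(list(rate = rate, x_breaks = x_breaks, y_breaks = y_breaks,
                 bin = bin, bin_x = diff(x_breaks[1:2]),
                 bin_y = diff(y_breaks[1:2]), smooth = smooth),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map: %d x %d bins of %g cm, peak %.2f Hz, %d masked>\n",
              nrow(x$rate), ncol(x$rate), x$bin,
              suppressWarnings(max(x$rate, na.rm = TRUE)),
              sum(is.na(x$rate))))
  invisible(x)
}

# Separable Gaussian smoothing with renormalization at edges (and around
# masked bins), sigma in bin units.
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  sm1 <- function(m) {  # smooth along rows (first dimension)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wgt <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      src <- pmin(pmax(seq_len(n) + o, 1), n)
      valid <- (seq_len(n) + o >= 1) & (seq_len(n) + o <= n)
      out[valid, ] <- out[valid, ] + k[o + r + 1] * m[src[valid], ]
      wgt[valid, ] <- wgt[valid, ] + k[o + r + 1]
    }
    out / wgt
  }
  t(sm1(t(sm1(mat))))
}

#' Plot a rate map
#'
#' @param object A [rate_map()].
#' @param ... Unused.
#' @return A ggplot object (filled raster, masked bins blank).
#' @export
autoplot.rate_map <- function(object, ...) {
  xc <- (object$x_breaks[-1] + object$x_breaks[-length(object$x_breaks)]) / 2
  yc <- (object$y_breaks[-1] + object$y_breaks[-length(object$y_breaks)]) / 2
  df <- expand.grid(x = xc, y = yc)
  df$rate <- as.vector(object$rate)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "Hz") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every spatial offset,
#' computed over the bins valid in both copies; offsets with fewer than
#' `min_overlap` valid pairs are `NA`.
#'
#' @param map A [rate_map()].
#' @param min_overlap Minimum number of overlapping valid bins per offset.
#' @return Matrix of size `(2 nx - 1) x (2 ny - 1)` of correlations, the
#'   zero offset at the center.
#' @export
autocorrelogram <- function(map, min_overlap = 20) {
  m <- map$rate
  nx <- nrow(m)
  ny <- ncol(m)
  out <- matrix(NA_real_, 2 * nx - 1, 2 * ny - 1)
  for (ox in -(nx - 1):(nx - 1)) {
    x1 <- max(1, 1 + ox):min(nx, nx + ox)
    x2 <- x1 - ox
    for (oy in -(ny - 1):(ny - 1)) {
      y1 <- max(1, 1 + oy):min(ny, ny + oy)
      y2 <- y1 - oy
      a <- m[x1, y1]
      b <- m[x2, y2]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) >= min_overlap) {
        va <- a[ok]
        vb <- b[ok]
        if (stats::sd(va) > 0 && stats::sd(vb) > 0) {
          out[ox + nx, oy + ny] <- stats::cor(va, vb)
        }
      }
    }
  }
  out
}

# Bilinear sampling of matrix `m` (unit-spaced grid, 1-based coordinates) at
# real-valued coordinates; NA outside or where all four neighbors are NA.
bilinear_sample <- function(m, xq, yq) {
  nx <- nrow(m)
  ny <- ncol(m)
  x0 <- floor(xq)
  y0 <- floor(yq)
  fx <- xq - x0
  fy <- yq - y0
  out <- rep(NA_real_, length(xq))
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  if (!any(ok)) return(out)
  i00 <- cbind(x0[ok], y0[ok])
  i10 <- cbind(x0[ok] + 1, y0[ok])
  i01 <- cbind(x0[ok], y0[ok] + 1)
  i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
  w00 <- (1 - fx[ok]) * (1 - fy[ok])
  w10 <- fx[ok] * (1 - fy[ok])
  w01 <- (1 - fx[ok]) * fy[ok]
  w11 <- fx[ok] * fy[ok]
  v00 <- m[i00]; v10 <- m[i10]; v01 <- m[i01]; v11 <- m[i11]
  num <- ifelse(is.na(v00), 0, w00 * v00) + ifelse(is.na(v10), 0, w10 * v10) +
    ifelse(is.na(v01), 0, w01 * v01) + ifelse(is.na(v11), 0, w11 * v11)
  den <- ifelse(is.na(v00), 0, w00) + ifelse(is.na(v10), 0, w10) +
    ifelse(is.na(v01), 0, w01) + ifelse(is.na(v11), 0, w11)
  val <- ifelse(den > 0.5, num / den, NA_real_)
  out[ok] <- val
  out
}

#' Gridness score of a rate map
#'
#' Rotational-symmetry statistic of the map's spatial autocorrelogram: the
#' autocorrelogram is rotated by 30-150 degrees and correlated with itself
#' over an annulus that excludes the central peak; the score is the lowest
#' of the 60- and 120-degree correlations minus the highest of the 30-, 90-
#' and 150-degree correlations. Hexagonal maps score strongly positive
#' (the score lives on a -2..2 scale), white noise near zero in
#' expectation, and square lattices negative (their 90-degree symmetry is
#' penalized by construction). The annulus inner radius is where the
#' azimuthally averaged autocorrelation first drops below 0.2 (the central
#' peak's extent); the outer radius is the largest fully covered circle.
#'
#' @param map A [rate_map()] (non-degenerate: some variation required).
#' @return Gridness score (scalar).
#' @export
gridness <- function(map) {
  ac <- autocorrelogram(map)
  if (all(is.na(ac)) || stats::sd(ac, na.rm = TRUE) == 0) {
    stop("degenerate (constant) rate map: gridness undefined", call. = FALSE)
  }
  cx <- (nrow(ac) + 1) / 2
  cy <- (ncol(ac) + 1) / 2
  ix <- row(ac) - cx
  iy <- col(ac) - cy
  rr <- sqrt(ix^2 + iy^2)
  # central peak extent from the azimuthal mean profile
  prof_r <- 0:floor(min(cx, cy) - 1)
  prof <- vapply(prof_r, function(r) {
    sel <- rr >= r - 0.5 & rr < r + 0.5
    mean(ac[sel], na.rm = TRUE)
  }, numeric(1))
  below <- which(prof < 0.2)
  r_in <- if (length(below) > 0) prof_r[below[1]] else ceiling(min(cx, cy) / 4)
  r_out <- floor(min(cx, cy)) - 1
  if (r_in >= r_out) r_in <- max(1, r_out - 3)
  annulus <- which(rr > r_in & rr <= r_out & !is.na(ac))
  base_vals <- ac[annulus]
  axc <- ix[annulus]
  ayc <- iy[annulus]
  rot_cor <- vapply(c(30, 60, 90, 120, 150) * pi / 180, function(a) {
    xr <- cos(a) * axc - sin(a) * ayc + cx
    yr <- sin(a) * axc + cos(a) * ayc + cy
    v <- bilinear_sample(ac, xr, yr)
    ok <- !is.na(v)
    stats::cor(base_vals[ok], v[ok])
  }, numeric(1))
  min(rot_cor[c(2, 4)]) - max(rot_cor[c(1, 3, 5)])
}

#' Compression scan: best rescaling match between two rate maps
#'
#' Quantifies how much one configuration's firing pattern must be stretched
#' along an axis to best match the other's. For every candidate compression
#' percentage `p` -- expressed as a fraction of the barrier `shift`, so
#' that 100 % rescales map B's extent by the full shift -- map B is
#' rescaled along the axis, resampled (bilinear) onto map A's bin grid
#' over the overlapping extent, and the squared Pearson correlation of the
#' firing rates over the jointly valid bins is recorded. The location of
#' the maximum is the best-match compression percentage: near 0 % when the
#' patterns already align (moving feature system), near 100 % when the
#' pattern compressed by the full barrier shift (static feature system).
#'
#' @param map_a,map_b [rate_map()]s of the same cell under configurations A
#'   and B.
#' @param axis `"y"` (the shifted dimension by default) or `"x"`.
#' @param range Percentage range scanned, default -20 to 120.
#' @param step Scan resolution in percentage points.
#' @param shift Barrier shift (cm) that defines 100 %.
#' @param min_overlap Minimum jointly valid bins for a correlation.
#' @return A tibble of class `compression_scan` with columns `percent` and
#'   `r2`; the argmax percentage is available via [glance.compression_scan()]
#'   and as attribute `argmax`.
#' @export
compression_scan <- function(map_a, map_b, axis = c("y", "x"),
                             range = c(-20, 120), step = 0.5, shift = 50,
                             min_overlap = 50) {
  axis <- match.arg(axis)
  stopifnot(inherits(map_a, "rate_map"), inherits(map_b, "rate_map"))
  if (all(is.na(map_a$rate)) || all(is.na(map_b$rate)) ||
      stats::sd(map_a$rate, na.rm = TRUE) == 0 ||
      stats::sd(map_b$rate, na.rm = TRUE) == 0) {
    stop("degenerate (constant or empty) rate map: correlation undefined",
         call. = FALSE)
  }
  pcts <- seq(range[1], range[2], by = step)
  # A-grid bin centers in cm
  xc <- (map_a$x_breaks[-1] + map_a$x_breaks[-length(map_a$x_breaks)]) / 2
  yc <- (map_a$y_breaks[-1] + map_a$y_breaks[-length(map_a$y_breaks)]) / 2
  grid <- expand.grid(x = xc, y = yc)
  va <- as.vector(map_a$rate)
  ext_b <- c(max(map_b$x_breaks), max(map_b$y_breaks))
  r2 <- vapply(pcts, function(p) {
    stretch_to <- if (axis == "y") ext_b[2] + p / 100 * shift else
      ext_b[1] + p / 100 * shift
    if (stretch_to <= 0) return(NA_real_)
    sc <- if (axis == "y") ext_b[2] / stretch_to else ext_b[1] / stretch_to
    bx <- if (axis == "x") grid$x * sc else grid$x
    by <- if (axis == "y") grid$y * sc else grid$y
    vb <- bilinear_sample(map_b$rate, bx / map_b$bin_x + 0.5,
                          by / map_b$bin_y + 0.5)
    inside <- (if (axis == "y") grid$y <= stretch_to else grid$x <= stretch_to)
    ok <- !is.na(va) & !is.na(vb) & inside
    if (sum(ok) < min_overlap) return(NA_real_)
    if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) return(NA_real_)
    stats::cor(va[ok], vb[ok])^2
  }, numeric(1))
  out <- tibble::tibble(percent = pcts, r2 = r2)
  class(out) <- c("compression_scan", class(out))
  attr(out, "axis") <- axis
  attr(out, "argmax") <- pcts[which.max(r2)]
  out
}

#' Summarize a compression scan
#'
#' @param x A [compression_scan()] result.
#' @param ... Unused.
#' @return One-row tibble with `argmax_percent`, `r2_max` and the scanned
#'   axis.
#' @export
glance.compression_scan <- function(x, ...) {
  i <- which.max(x$r2)
  tibble::tibble(argmax_percent = x$percent[i], r2_max = x$r2[i],
                 axis = attr(x, "axis"))
}

#' Plot a compression scan
#'
#' @param object A [compression_scan()] result.
#' @param ... Unused.
#' @return A ggplot object: correlation against compression percentage with
#'   the argmax marked.
#' @export
autoplot.compression_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$percent, .data$r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "argmax"),
                        linetype = "dashed") +
    ggplot2::labs(x = "compression (% of barrier shift)",
                  y = expression(r^2))
}

#' Euclidean error between a location estimate and the true trajectory
#'
#' Per-timestep Euclidean distance between estimated and true position.
#' When both series stay inside the arena the error cannot exceed the box
#' diagonal; a path-integrated estimate under biased noise is not so
#' constrained and can drift beyond it.
#'
#' @param est Location estimate with columns `t`, `x_hat`, `y_hat`.
#' @param truth Trajectory with columns `t`, `x`, `y`; must align with
#'   `est` row for row.
#' @return Tibble with columns `t` and `error` (cm).
#' @export
euclidean_error <- function(est, truth) {
  if (nrow(est) != nrow(truth)) {
    stop("estimate and trajectory lengths differ", call. = FALSE)
  }
  tibble::tibble(
    t = truth$t,
    error = sqrt((est$x_hat - truth$x)^2 + (est$y_hat - truth$y)^2)
  )
}

#' Across-trial mean and spread of error time series
#'
#' @param err Numeric matrix, trials x time, of per-timestep errors.
#' @param t Time stamps (length `ncol(err)`).
#' @return Tibble with columns `t`, `mean`, `sd`, `lower`, `upper`
#'   (mean +/- 1 SD).
#' @export
error_band <- function(err, t = seq_len(ncol(err))) {
  stopifnot(is.matrix(err), length(t) == ncol(err))
  mu <- colMeans(err)
  sg <- apply(err, 2, stats::sd)
  tibble::tibble(t = t, mean = mu, sd = sg, lower = mu - sg, upper = mu + sg)
}

#' Plot a trajectory
#'
#' @param object A [synthesize_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot object of the path in the arena.
#' @export
autoplot.ts_trajectory <- function(object, ...) {
  box <- attr(object, "config")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(linewidth = 0.1, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
  if (!is.null(box)) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = box$width_x,
                               ymin = 0, ymax = box$length_y,
                               fill = NA, colour = "black")
  }
  p
}

#' Plot a location-estimate series over time
#'
#' @param object An estimate from [estimate_path_moving()] or
#'   [estimate_path_static()].
#' @param ... Unused.
#' @return A ggplot object of the estimated path.
#' @export
autoplot.ts_location_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_hat, .data$y_hat)) +
    ggplot2::geom_path(linewidth = 0.1, alpha = 0.6, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "estimated x (cm)", y = "estimated y (cm)")
}
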