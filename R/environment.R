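#' Box configuration for the two-barrier-shift arena
#'
#' Describes the simulated box in one of its two layouts: configuration "A"
#' is the 150 cm x 150 cm square arena, configuration "B" the same arena
#' after the far (north) barrier has been shifted in by 50 cm, giving a
#' 150 cm x 100 cm rectangle. Walls are 50 cm high and the simulated eye
#' sits 2.5 cm above the ground. Nine visual features are scattered on each
#' of the six surfaces (ground, ceiling, four walls), 54 in total.
#'
#' @param label "A" (square, 150 x 150 cm) or "B" (compressed, 150 x 100 cm).
#' @param width_x,length_y Box extent in x and y (cm). Defaults follow the
#'   chosen `label`; override only for sensitivity experiments.
#' @param wall_height Barrier height (cm).
#' @param eye_height Eye height above the ground plane (cm); must lie strictly
#'   between 0 and `wall_height`.
#' @param features_per_surface Number of visual features per surface.
#' @return An object of class `box_config`: a list with the fields above.
#' @examples
#' box_config("A")
#' box_config("B")$length_y
#' @export
box_config <- function(label = c("A", "B"),
                       width_x = 150,
                       length_y = NULL,
                       wall_height = 50,
                       eye_height = 2.5,
                       features_per_surface = 9) {
  label <- match.arg(label)
  if (is.null(length_y)) {
    length_y <- if (label == "A") 150 else 100
  }
  stopifnot(width_x > 0, length_y > 0, wall_height > 0,
            eye_height > 0, eye_height < wall_height,
            features_per_surface >= 1)
  structure(
    list(label = label, width_x = width_x, length_y = length_y,
         wall_height = wall_height, eye_height = eye_height,
         features_per_surface = features_per_surface),
    class = "box_config"
  )
}

#' @export
print.box_config <- function(x, ...) {
  cat(sprintf("<box_config %s: %g x %g cm, walls %g cm, eye %g cm, %d features/surface>\n",
              x$label, x$width_x, x$length_y, x$wall_height, x$eye_height,
              x$features_per_surface))
  invisible(x)
}

surface_names <- c("ground", "ceiling", "N-wall", "S-wall", "W-wall", "E-wall")

#' Build the box world with features on all six surfaces
#'
#' Places `features_per_surface` visual features uniformly at random on each
#' surface of the configuration-A box. The derived configuration B reuses the
#' same features: features on the shifted north barrier move rigidly with it
#' (keeping their within-wall position), and features that fall outside the
#' compressed box volume (ground, ceiling, west and east wall features beyond
#' the new barrier plane) are flagged invisible in B. No ray-cast occlusion is
#' applied beyond this volume test. Ceiling features are generated so the
#' feature budget matches the arena description, but neither location
#' estimator consumes them: the moving system reads ground features only and
#' the static system reads wall features only.
#'
#' @param config A [box_config()]; features are always laid out in the "A"
#'   geometry, and the configuration-B view is derived from it.
#' @param seed Integer seed making the feature layout reproducible.
#' @return An object of class `box_environment`: list with elements
#'   `config_a`, `config_b` (both `box_config`) and `features`, a tibble with
#'   columns `id`, `surface`, `x`, `y`, `z` (configuration-A position, cm),
#'   `x_b`, `y_b`, `z_b` (position in configuration B; identical except for
#'   barrier features that moved) and `visible_in_b`.
#' @examples
#' env <- build_environment(box_config("A"), seed = 1)
#' dplyr::count(env$features, surface)
#' @export
build_environment <- function(config = box_config("A"), seed = 1) {
  stopifnot(inherits(config, "box_config"))
  if (config$label != "A") {
    config <- box_config("A", width_x = config$width_x,
                         wall_height = config$wall_height,
                         eye_height = config$eye_height,
                         features_per_surface = config$features_per_surface)
  }
  m <- config$features_per_surface
  wx <- config$width_x
  ly <- config$length_y
  h <- config$wall_height

  if (!is.null(seed)) set.seed(seed)
  one_surface <- function(surface) {
    u <- stats::runif(m)
    v <- stats::runif(m)
    switch(surface,
      "ground"  = tibble::tibble(x = u * wx, y = v * ly, z = 0),
      "ceiling" = tibble::tibble(x = u * wx, y = v * ly, z = h),
      "N-wall"  = tibble::tibble(x = u * wx, y = ly, z = v * h),
      "S-wall"  = tibble::tibble(x = u * wx, y = 0, z = v * h),
      "W-wall"  = tibble::tibble(x = 0, y = u * ly, z = v * h),
      "E-wall"  = tibble::tibble(x = wx, y = u * ly, z = v * h)
    )
  }
  features <- purrr::map_dfr(surface_names, function(s) {
    dplyr::mutate(one_surface(s), surface = s, .before = 1)
  })
  features <- dplyr::mutate(features,
                            id = dplyr::row_number(), .before = 1)

  config_b <- box_config("B", width_x = wx, wall_height = h,
                         eye_height = config$eye_height,
                         features_per_surface = m)
  ly_b <- config_b$length_y
  # Barrier features ride along with the shifted north wall; everything else
  # keeps its world position and is hidden when outside the B volume.
  features <- dplyr::mutate(
    features,
    x_b = .data$x,
    y_b = ifelse(.data$surface == "N-wall", ly_b, .data$y),
    z_b = .data$z,
    visible_in_b = .data$y_b <= ly_b
  )

  structure(
    list(config_a = config, config_b = config_b, features = features),
    class = "box_environment"
  )
}

#' @export
print.box_environment <- function(x, ...) {
  cat(sprintf("<box_environment: %d features; A %g x %g cm, B %g x %g cm; %d visible in B>\n",
              nrow(x$features),
              x$config_a$width_x, x$config_a$length_y,
              x$config_b$width_x, x$config_b$length_y,
              sum(x$features$visible_in_b)))
  invisible(x)
}

#' Feature table of an environment under one configuration
#'
#' @param env A [build_environment()] result.
#' @param config "A" or "B". Under "B", barrier features appear at their
#'   shifted positions and occluded features are dropped.
#' @return Tibble with columns `id`, `surface`, `x`, `y`, `z`.
#' @export
env_features <- function(env, config = c("A", "B")) {
  stopifnot(inherits(env, "box_environment"))
  config <- match.arg(config)
  f <- env$features
  if (config == "A") {
    dplyr::select(f, "id", "surface", "x", "y", "z")
  } else {
    f |>
      dplyr::filter(.data$visible_in_b) |>
      dplyr::transmute(.data$id, .data$surface,
                       x = .data$x_b, y = .data$y_b, z = .data$z_b)
  }
}

#' Active box of an environment under one configuration
#'
#' @inheritParams env_features
#' @return The `box_config` in force under `config`.
#' @export
env_config <- function(env, config = c("A", "B")) {
  stopifnot(inherits(env, "box_environment"))
  config <- match.arg(config)
  if (config == "A") env$config_a else env$config_b
}

#' Features geometrically available from a pose
#'
#' Returns the features a rat at the given pose can use, i.e. those whose
#' elevation falls within the vertical field of view (120 degrees total,
#' so +/-60 degrees about the horizon). Azimuth never excludes a feature:
#' the full 360 degrees are taken as available horizontally, standing in for
#' short-term memory of feature angles across head turns. Under
#' configuration B, features occluded by the shifted barrier are dropped
#' before the field-of-view test.
#'
#' @param env A [build_environment()] result.
#' @param x,y Rat position (cm); must lie inside the active box.
#' @param phi Heading in radians (used only to report egocentric azimuth).
#' @param config "A" or "B".
#' @param v_fov Vertical field of view in degrees (total aperture).
#' @return Tibble of available features with columns `id`, `surface`,
#'   `group` ("ground", "wall" or "ceiling"), `azimuth`, `elevation`
#'   (radians, egocentric camera angles) and `bearing` (allocentric, radians).
#' @examples
#' env <- build_environment(box_config("A"), seed = 1)
#' obs <- available_features(env, x = 75, y = 75, phi = 0)
#' table(obs$group)
#' @export
available_features <- function(env, x, y, phi = 0, config = c("A", "B"),
                               v_fov = 120) {
  stopifnot(inherits(env, "box_environment"), length(x) == 1, length(y) == 1)
  config <- match.arg(config)
  box <- env_config(env, config)
  if (x < 0 || x > box$width_x || y < 0 || y > box$length_y) {
    stop("pose (", x, ", ", y, ") lies outside the ", config,
         " box; invalid trajectory state", call. = FALSE)
  }
  f <- env_features(env, config)
  dx <- f$x - x
  dy <- f$y - y
  dz <- f$z - box$eye_height
  rho <- sqrt(dx^2 + dy^2)
  elevation <- atan2(dz, rho)
  bearing <- atan2(dy, dx)
  out <- tibble::tibble(
    id = f$id,
    surface = f$surface,
    group = dplyr::case_when(
      f$surface == "ground" ~ "ground",
      f$surface == "ceiling" ~ "ceiling",
      TRUE ~ "wall"
    ),
    azimuth = wrap_angle(bearing - phi),
    elevation = elevation,
    bearing = bearing
  )
  dplyr::filter(out, abs(.data$elevation) <= (v_fov / 2) * pi / 180)
}
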