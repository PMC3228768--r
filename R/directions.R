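# Candidate target directions over the frontal hemisphere.
#
# Directions are parametrized by azimuth (degrees, positive to the bat's
# right) and elevation (degrees, positive up), both in [-90, 90].  All
# geometry is done on 3-D unit vectors with the x axis pointing forward,
# y to the right and z up, which keeps rotations and distances free of
# polar artefacts.

#' Convert azimuth/elevation to unit vectors
#'
#' @param azimuth_deg,elevation_deg numeric vectors of angles in degrees;
#'   azimuth is positive towards the right, elevation positive up.
#' @return a matrix with columns `x` (forward), `y` (right), `z` (up),
#'   one row per direction.
#' @export
dir_to_unit <- function(azimuth_deg, elevation_deg) {
  az <- deg2rad(azimuth_deg)
  el <- deg2rad(elevation_deg)
  cbind(x = cos(el) * cos(az), y = cos(el) * sin(az), z = sin(el))
}

#' Convert unit vectors back to azimuth/elevation
#'
#' @param u a numeric matrix with columns x (forward), y (right), z (up).
#' @return a data.frame with columns `azimuth_deg`, `elevation_deg`.
#' @export
unit_to_dir <- function(u) {
  u <- rbind(u)
  z <- pmin(1, pmax(-1, u[, 3]))
  data.frame(azimuth_deg  = rad2deg(atan2(u[, 2], u[, 1])),
             elevation_deg = rad2deg(asin(z)))
}

in_frontal_hemisphere <- function(azimuth_deg, elevation_deg, tol = 1e-9) {
  dir_to_unit(azimuth_deg, elevation_deg)[, 1] >= -tol
}

#' Equal-area direction grid on the frontal hemisphere
#'
#' Builds a deterministic set of `n` candidate target directions,
#' approximately uniformly distributed (equal-area) over the frontal
#' hemisphere using a golden-angle spiral in the cosine of the off-axis
#' angle.  The grid is the discrete hypothesis space over which the
#' localization posterior is computed; the reference configuration uses
#' 3252 directions.
#'
#' @param n number of directions (>= 1).  `n = 1` returns the single
#'   on-axis direction (0, 0).
#' @return an object of class `direction_grid`: a data.frame with columns
#'   `direction_id`, `azimuth_deg`, `elevation_deg` and a `units` attribute
#'   holding the corresponding unit vectors.
#' @examples
#' g <- make_direction_grid(500)
#' nrow(g)
#' @export
make_direction_grid <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stopf("`n` must be a single integer >= 1")
  }
  n <- as.integer(n)
  if (n == 1L) {
    u <- dir_to_unit(0, 0)
  } else {
    i <- seq_len(n) - 1L
    # equal-area in cos(psi) over the hemisphere: cos(psi) in (0, 1)
    cpsi <- 1 - (i + 0.5) / n
    spsi <- sqrt(pmax(0, 1 - cpsi^2))
    phi  <- i * pi * (3 - sqrt(5))          # golden angle
    u <- cbind(x = cpsi, y = spsi * cos(phi), z = spsi * sin(phi))
  }
  ae <- unit_to_dir(u)
  g <- data.frame(direction_id = seq_len(n),
                  azimuth_deg  = ae$azimuth_deg,
                  elevation_deg = ae$elevation_deg)
  attr(g, "units") <- u
  class(g) <- c("direction_grid", "data.frame")
  g
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf("direction_grid: %d directions on the frontal hemisphere\n",
              nrow(x)))
  cat(sprintf("  chance-level entropy: %.2f bits\n", log2(nrow(x))))
  invisible(x)
}

grid_units <- function(grid) {
  u <- attr(grid, "units")
  if (is.null(u)) u <- dir_to_unit(grid$azimuth_deg, grid$elevation_deg)
  u
}

#' Lambert azimuthal equal-area projection
#'
#' Projects frontal-hemisphere directions onto the plane, centred on the
#' forward axis (0, 0), preserving solid angle.  Used for all spatial maps.
#'
#' @param azimuth_deg,elevation_deg directions to project (degrees).
#' @return a data.frame with planar columns `x` (rightward) and `y` (upward);
#'   the forward direction maps to (0, 0) and the 90-degree rim to radius
#'   sqrt(2).
#' @export
lambert_project <- function(azimuth_deg, elevation_deg) {
  u <- dir_to_unit(azimuth_deg, elevation_deg)
  if (any(u[, 1] < -1e-9)) {
    stopf("lambert_project is defined on the frontal hemisphere only")
  }
  s <- sqrt(2 / (1 + pmax(u[, 1], 0)))
  data.frame(x = s * u[, 2], y = s * u[, 3])
}

#' Great-circle distance between directions
#'
#' @param az1,el1,az2,el2 angles in degrees; vectors are recycled.
#' @return angular separation in degrees.
#' @export
great_circle_distance <- function(az1, el1, az2, el2) {
  n <- max(length(az1), length(el1), length(az2), length(el2))
  u1 <- dir_to_unit(rep_len(az1, n), rep_len(el1, n))
  u2 <- dir_to_unit(rep_len(az2, n), rep_len(el2, n))
  d <- pmin(1, pmax(-1, rowSums(u1 * u2)))
  rad2deg(acos(d))
}

# Nearest-neighbour great-circle spacing for each grid point, degrees.
grid_nn_spacing <- function(grid) {
  u <- grid_units(grid)
  g <- u %*% t(u)
  diag(g) <- -Inf
  rad2deg(acos(pmin(1, pmax(-1, apply(g, 1, max)))))
}

#' Rotation matrix for an (azimuth, elevation) offset
#'
#' Composes a rotation about the up axis (azimuth) with a rotation about the
#' right axis (elevation) such that the forward direction (0, 0) maps exactly
#' to (`daz`, `del`).  Applied to row unit vectors as `u %*% t(R)`.
#'
#' @param daz_deg,del_deg rotation offsets in degrees.
#' @return a 3x3 orthonormal matrix.
#' @export
rotation_matrix <- function(daz_deg, del_deg) {
  a <- deg2rad(daz_deg)
  e <- deg2rad(del_deg)
  r_az <- rbind(c(cos(a), -sin(a), 0),
                c(sin(a),  cos(a), 0),
                c(0,       0,      1))
  r_el <- rbind(c(cos(e), 0, -sin(e)),
                c(0,      1,  0),
                c(sin(e), 0,  cos(e)))
  r_az %*% r_el
}

#' Export a direction grid to CSV
#'
#' Writes columns `direction_id, azimuth_deg, elevation_deg`.
#'
#' @param grid a `direction_grid`.
#' @param path output file path.
#' @export
write_direction_grid <- function(grid, path) {
  data.table::fwrite(as.data.frame(grid)[, c("direction_id", "azimuth_deg",
                                             "elevation_deg")], path)
  invisible(path)
}
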