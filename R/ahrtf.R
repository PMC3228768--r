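# Synthetic directional sensitivity (AHRTF components) and pinna motion.
#
# The combined emission + ear directionality determines the expected
# received level for every target direction.  Measured or boundary-element
# simulated patterns can be loaded from CSV; a parametric single-lobe
# generator stands in for them when none are supplied.  Pinna motion is
# modelled as a rigid rotation of the ear pattern along an oblique arc,
# one ear sweeping up while the other sweeps down, with the emission
# pattern held fixed.

#' Construct a directivity pattern
#'
#' Low-level constructor wrapping an arbitrary gain rule.  Most users will
#' call [make_parametric_beam()] or [load_directivity()] instead.
#'
#' @param gain_fun function taking an n x 3 matrix of unit vectors
#'   (forward/right/up) and returning a numeric vector of gains in dB.
#' @param frequency_khz nominal frequency the pattern describes (metadata).
#' @param label short description used in printing.
#' @return an object of class `directivity_pattern`.
#' @export
directivity_pattern <- function(gain_fun, frequency_khz = 75, label = "custom") {
  stopifnot(is.function(gain_fun))
  structure(list(gain_fun = gain_fun, frequency_khz = frequency_khz,
                 label = label),
            class = "directivity_pattern")
}

#' @export
print.directivity_pattern <- function(x, ...) {
  cat(sprintf("directivity_pattern (%s, %g kHz)\n", x$label, x$frequency_khz))
  invisible(x)
}

#' Evaluate a directivity pattern
#'
#' @param pattern a `directivity_pattern`.
#' @param azimuth_deg,elevation_deg directions at which to evaluate (degrees).
#' @return gains in dB (0 dB at the pattern peak for generated patterns).
#' @export
pattern_gain <- function(pattern, azimuth_deg, elevation_deg) {
  pattern$gain_fun(dir_to_unit(azimuth_deg, elevation_deg))
}

pattern_gain_units <- function(pattern, u) pattern$gain_fun(u)

#' Parametric single-lobe beam
#'
#' Generates a smooth, circularly symmetric Gaussian lobe in off-axis angle,
#' peak-normalized to 0 dB at the boresight, optionally with a raised-cosine
#' side lobe.  This is the synthetic stand-in for boundary-element simulated
#' emission and ear patterns of a CF bat head at ~75 kHz.
#'
#' @param beamwidth_deg full half-power beamwidth in degrees (> 0): the gain
#'   is -3 dB at `beamwidth_deg / 2` off boresight.
#' @param boresight_az,boresight_el boresight direction in degrees.
#' @param sidelobe_level_db peak level of an optional side lobe in dB
#'   (<= 0), or `NULL` for a pure single lobe.
#' @param sidelobe_offset_deg off-axis angle of the side-lobe peak; the lobe
#'   has compact support of width `beamwidth_deg` about this angle.
#' @param frequency_khz nominal frequency metadata.
#' @return a `directivity_pattern`.
#' @examples
#' b <- make_parametric_beam(40)
#' pattern_gain(b, 0, 0)    # 0 dB at boresight
#' pattern_gain(b, 20, 0)   # -3 dB at the half-power angle
#' @export
make_parametric_beam <- function(beamwidth_deg, boresight_az = 0,
                                 boresight_el = 0, sidelobe_level_db = NULL,
                                 sidelobe_offset_deg = 60,
                                 frequency_khz = 75) {
  check_number(beamwidth_deg, "beamwidth_deg")
  if (beamwidth_deg <= 0) stopf("`beamwidth_deg` must be positive")
  if (!is.null(sidelobe_level_db)) {
    check_number(sidelobe_level_db, "sidelobe_level_db", upper = 0)
    check_number(sidelobe_offset_deg, "sidelobe_offset_deg", lower = 0)
  }
  b <- drop(dir_to_unit(boresight_az, boresight_el))
  half <- beamwidth_deg / 2

  gain_psi_db <- function(psi_deg) {
    main_db <- -3 * (psi_deg / half)^2
    p_lin <- 10^(main_db / 10)
    if (!is.null(sidelobe_level_db)) {
      w <- (psi_deg - sidelobe_offset_deg) / beamwidth_deg   # support |w| < 1/2
      s <- ifelse(abs(w) < 0.5, cos(pi * w)^2, 0)
      p_lin <- p_lin + 10^(sidelobe_level_db / 10) * s
    }
    10 * log10(p_lin)
  }
  # peak normalization over a dense off-axis sweep (peak is at 0 for any
  # sidelobe_level_db <= 0, but normalize defensively)
  peak_db <- max(gain_psi_db(seq(0, 180, by = 0.05)))

  directivity_pattern(
    gain_fun = function(u) {
      psi <- rad2deg(acos(pmin(1, pmax(-1, drop(u %*% b)))))
      gain_psi_db(psi) - peak_db
    },
    frequency_khz = frequency_khz,
    label = sprintf("parametric beam, %.3g deg half-power", beamwidth_deg)
  )
}

#' Load a directivity pattern from CSV
#'
#' Reads a gain grid with columns `azimuth_deg`, `elevation_deg`, `gain_db`
#' forming a complete azimuth-elevation lattice over the frontal hemisphere,
#' re-normalizes it to a 0 dB peak, and returns a pattern that evaluates by
#' bilinear interpolation on the lattice (queries outside the lattice are
#' clamped to its edge).
#'
#' @param path CSV file path (header row required).
#' @param max_gap_deg largest tolerated spacing between consecutive lattice
#'   lines and between the lattice edge and +/-90 degrees; larger gaps are a
#'   format error.
#' @return a `directivity_pattern`.
#' @export
load_directivity <- function(path, max_gap_deg = 10) {
  if (!file.exists(path)) stopf("directivity file not found: %s", path)
  d <- utils::read.csv(path)
  need <- c("azimuth_deg", "elevation_deg", "gain_db")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stopf("directivity file %s lacks required column(s): %s",
          path, paste(miss, collapse = ", "))
  }
  if (nrow(d) == 0) stopf("directivity file %s is empty", path)
  if (any(!is.finite(d$gain_db))) stopf("non-finite gains in %s", path)

  az <- sort(unique(d$azimuth_deg))
  el <- sort(unique(d$elevation_deg))
  if (nrow(d) != length(az) * length(el)) {
    stopf("directivity grid in %s is not a complete azimuth-elevation lattice",
          path)
  }
  gaps <- c(diff(az), diff(el),
            min(az) + 90, 90 - max(az), min(el) + 90, 90 - max(el))
  if (max(gaps) > max_gap_deg) {
    stopf("directivity grid in %s has coverage gaps larger than %g degrees",
          path, max_gap_deg)
  }
  z <- matrix(NA_real_, length(el), length(az))
  z[cbind(match(d$elevation_deg, el), match(d$azimuth_deg, az))] <-
    d$gain_db - max(d$gain_db)          # peak-normalize to 0 dB

  directivity_pattern(
    gain_fun = function(u) {
      ae <- unit_to_dir(u)
      xq <- pmin(max(az), pmax(min(az), ae$azimuth_deg))
      yq <- pmin(max(el), pmax(min(el), ae$elevation_deg))
      pracma::interp2(az, el, z, xq, yq, method = "linear")
    },
    label = sprintf("loaded from %s", basename(path))
  )
}

#' Export a directivity pattern to a CSV lattice
#'
#' Companion to [load_directivity()]; evaluates the pattern on a regular
#' azimuth-elevation lattice and writes `azimuth_deg, elevation_deg, gain_db`.
#'
#' @param pattern a `directivity_pattern`.
#' @param path output file path.
#' @param step_deg lattice spacing in degrees.
#' @export
write_directivity <- function(pattern, path, step_deg = 5) {
  g <- expand.grid(azimuth_deg = seq(-90, 90, by = step_deg),
                   elevation_deg = seq(-90, 90, by = step_deg))
  g$gain_db <- pattern_gain(pattern, g$azimuth_deg, g$elevation_deg)
  write_results(g, path)
  invisible(path)
}

#' Rigidly rotate a directivity pattern
#'
#' Emulates pinna motion: the rotated pattern evaluated at direction `d`
#' equals the original pattern at the inversely rotated direction, so the
#' lobe shape is preserved exactly (no re-normalization) and its peak moves
#' with the applied rotation.
#'
#' @param pattern a `directivity_pattern`.
#' @param daz_deg,del_deg rotation offsets in degrees (|offset| <= 90).
#' @return the rotated `directivity_pattern`.
#' @export
rotate_pattern <- function(pattern, daz_deg, del_deg) {
  check_number(daz_deg, "daz_deg", lower = -90, upper = 90)
  check_number(del_deg, "del_deg", lower = -90, upper = 90)
  r <- rotation_matrix(daz_deg, del_deg)
  f <- pattern$gain_fun
  directivity_pattern(
    gain_fun = function(u) f(u %*% r),   # u %*% r == rows of R^-1 u
    frequency_khz = pattern$frequency_khz,
    label = sprintf("%s [rotated %+g az, %+g el]",
                    pattern$label, daz_deg, del_deg)
  )
}

#' Pinna stroke trajectory
#'
#' Rigid-rotation offsets for one ear sweeping through its stroke arc.
#' Following reports for horseshoe bats, the default arc runs over 30
#' degrees at an oblique angle (+/-15 degrees in both azimuth and
#' elevation), the right ear sweeping up in elevation while the left
#' sweeps down (anti-phase).  The azimuth pairing of the two ears is not
#' settled in the literature; `az_convention` exposes both readings.
#'
#' @param arc_az_deg,arc_el_deg half-arc amplitudes in degrees; the offsets
#'   run from -arc to +arc (sign conventions per ear as described).
#' @param n_pos number of stroke positions (>= 1), linearly interpolated
#'   between the arc endpoints.
#' @param ear `"left"` or `"right"`.
#' @param az_convention `"mirrored"` (left ear azimuth runs opposite to the
#'   right ear, the default) or `"parallel"`.
#' @return an object of class `pinna_trajectory` with an `offsets` matrix
#'   (`n_pos` rows, columns `daz_deg`, `del_deg`).
#' @export
make_trajectory <- function(arc_az_deg = 15, arc_el_deg = 15, n_pos = 100,
                            ear = c("right", "left"),
                            az_convention = c("mirrored", "parallel")) {
  ear <- match.arg(ear)
  az_convention <- match.arg(az_convention)
  if (!is.numeric(n_pos) || length(n_pos) != 1L || n_pos < 1) {
    stopf("`n_pos` must be a single integer >= 1")
  }
  n_pos <- as.integer(n_pos)
  ramp <- seq(-1, 1, length.out = n_pos)
  if (n_pos == 1L) ramp <- 0          # degenerate stroke: arc midpoint
  el_sign <- if (ear == "right") 1 else -1
  az_sign <- if (ear == "right" || az_convention == "parallel") 1 else -1
  offsets <- cbind(daz_deg = az_sign * arc_az_deg * ramp,
                   del_deg = el_sign * arc_el_deg * ramp)
  structure(list(ear = ear, offsets = offsets, n_pos = n_pos,
                 arc_az_deg = arc_az_deg, arc_el_deg = arc_el_deg),
            class = "pinna_trajectory")
}

#' @export
print.pinna_trajectory <- function(x, ...) {
  cat(sprintf("pinna_trajectory: %s ear, %d positions, arc +/-%g az +/-%g el\n",
              x$ear, x$n_pos, x$arc_az_deg, x$arc_el_deg))
  invisible(x)
}

#' Default synthetic sonar-head model
#'
#' Bundles a default emission beam, laterally offset left/right ear beams and
#' anti-phase pinna trajectories into the set of components needed by
#' [build_templates()].  The ear boresights are offset to either side of the
#' midline so that the two ears carry binaural disparity.
#'
#' @param emission_beamwidth,ear_beamwidth full half-power beamwidths (deg).
#' @param ear_boresight_az,ear_boresight_el magnitude of the lateral azimuth
#'   offset (mirrored left/right) and common elevation of the ear boresights.
#' @param arc_az_deg,arc_el_deg,n_pos,az_convention passed to
#'   [make_trajectory()].
#' @param sidelobe_level_db,sidelobe_offset_deg optional ear side lobe.
#' @return a list with elements `emission`, `ear_left`, `ear_right`,
#'   `traj_left`, `traj_right`.
#' @export
default_ahrtf <- function(emission_beamwidth = 40, ear_beamwidth = 45,
                          ear_boresight_az = 20, ear_boresight_el = 10,
                          arc_az_deg = 15, arc_el_deg = 15, n_pos = 40,
                          az_convention = "mirrored",
                          sidelobe_level_db = NULL, sidelobe_offset_deg = 60) {
  list(
    emission  = make_parametric_beam(emission_beamwidth),
    ear_left  = make_parametric_beam(ear_beamwidth, -ear_boresight_az,
                                     ear_boresight_el,
                                     sidelobe_level_db, sidelobe_offset_deg),
    ear_right = make_parametric_beam(ear_beamwidth, ear_boresight_az,
                                     ear_boresight_el,
                                     sidelobe_level_db, sidelobe_offset_deg),
    traj_left  = make_trajectory(arc_az_deg, arc_el_deg, n_pos, "left",
                                 az_convention),
    traj_right = make_trajectory(arc_az_deg, arc_el_deg, n_pos, "right",
                                 az_convention)
  )
}
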