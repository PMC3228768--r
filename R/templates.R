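# Binaural expected-modulation templates and glint sampling.
#
# For each candidate direction the template holds the expected received
# level at the left and right ear across the pinna-stroke positions:
# emission gain plus the rigidly rotated ear gain, normalized to zero mean
# over all 2 * n_pos entries so that the unknown echo strength carries all
# absolute level.  One full ear stroke is taken to span one call duration;
# dominant glints sample the template at discrete times set by the insect
# flutter rate.

#' Build binaural templates for a direction grid
#'
#' @param emission,ear_left,ear_right `directivity_pattern` objects; the
#'   emission pattern is held fixed during the stroke, the ear patterns are
#'   rigidly rotated along their trajectories.
#' @param traj_left,traj_right `pinna_trajectory` objects of equal length.
#' @param grid a `direction_grid` of candidate target directions.
#' @return an object of class `binaural_templates`: a list with `levels`
#'   (array `n_dir` x 2 ears x `n_pos`, dB, zero mean per direction),
#'   `grid`, `n_pos`, and the per-direction normalization offsets that were
#'   subtracted.
#' @export
build_templates <- function(emission, ear_left, ear_right,
                            traj_left, traj_right, grid) {
  if (traj_left$n_pos != traj_right$n_pos) {
    stopf("left and right trajectories must have the same number of positions")
  }
  n_pos <- traj_left$n_pos
  u <- grid_units(grid)
  n_dir <- nrow(u)
  em <- pattern_gain_units(emission, u)
  levels <- array(NA_real_, c(n_dir, 2L, n_pos),
                  dimnames = list(NULL, c("left", "right"), NULL))
  for (j in seq_len(n_pos)) {
    rl <- rotation_matrix(traj_left$offsets[j, 1], traj_left$offsets[j, 2])
    rr <- rotation_matrix(traj_right$offsets[j, 1], traj_right$offsets[j, 2])
    levels[, 1L, j] <- em + pattern_gain_units(ear_left,  u %*% rl)
    levels[, 2L, j] <- em + pattern_gain_units(ear_right, u %*% rr)
  }
  offsets <- apply(levels, 1, mean)
  levels <- levels - offsets            # recycles over the first extent
  structure(list(levels = levels, grid = grid, n_pos = n_pos,
                 norm_offset_db = offsets),
            class = "binaural_templates")
}

#' @export
print.binaural_templates <- function(x, ...) {
  cat(sprintf(
    "binaural_templates: %d directions x 2 ears x %d stroke positions\n",
    dim(x$levels)[1], x$n_pos))
  dr <- template_dynamic_range(x)
  cat(sprintf("  dynamic range: mean %.1f dB (sd %.1f)\n",
              mean(dr), stats::sd(dr)))
  invisible(x)
}

#' Low-level glint schedule constructor
#'
#' @param sample_times sorted times in seconds; generated schedules keep
#'   them in `[0, call_duration)`, the constructor also admits the closed
#'   endpoint (the end of the ear stroke).
#' @param flutter_rate_hz flutter rate the schedule derives from.
#' @param call_duration_s call/echo duration in seconds.
#' @param mode `"regular"` or `"random"`.
#' @return an object of class `glint_schedule`.
#' @export
glint_schedule <- function(sample_times, flutter_rate_hz,
                           call_duration_s = 0.05,
                           mode = c("regular", "random")) {
  mode <- match.arg(mode)
  if (length(sample_times) == 0) stopf("a glint schedule cannot be empty")
  if (is.unsorted(sample_times)) stopf("sample times must be sorted")
  if (any(sample_times < 0) || any(sample_times > call_duration_s)) {
    stopf("sample times must lie within the call duration")
  }
  structure(list(sample_times = as.numeric(sample_times),
                 flutter_rate_hz = flutter_rate_hz,
                 call_duration_s = call_duration_s, mode = mode),
            class = "glint_schedule")
}

#' Dominant-glint sampling schedule
#'
#' A target fluttering at `f` Hz produces one dominant glint per wingbeat,
#' i.e. `f * D` sample times within a call of duration `D` (1 to 10 glints
#' for 20-200 Hz at 50 ms).  In regular mode the glints are spaced exactly
#' `1/f` apart with the first drawn uniformly in `[0, 0.5/f)`; in random
#' mode the same number of times is drawn uniformly over the call and
#' sorted.  Uses the current RNG state.
#'
#' @param flutter_rate_hz insect wingbeat rate in Hz (> 0).
#' @param call_duration_s call/echo duration in seconds (> 0, default 50 ms).
#' @param mode `"regular"` or `"random"` glint spacing.
#' @param t0 optional fixed first-sample time (regular mode), mainly for
#'   testing; by default it is drawn.
#' @return a `glint_schedule`.
#' @examples
#' set.seed(1)
#' length(make_glint_schedule(100)$sample_times)  # 5 glints in 50 ms
#' @export
make_glint_schedule <- function(flutter_rate_hz, call_duration_s = 0.05,
                                mode = c("regular", "random"), t0 = NULL) {
  mode <- match.arg(mode)
  check_number(flutter_rate_hz, "flutter_rate_hz")
  check_number(call_duration_s, "call_duration_s")
  if (flutter_rate_hz <= 0) stopf("`flutter_rate_hz` must be positive")
  if (call_duration_s <= 0) stopf("`call_duration_s` must be positive")
  period <- 1 / flutter_rate_hz
  if (is.null(t0)) t0 <- stats::runif(1, 0, 0.5 * period)
  times <- seq(t0, call_duration_s + period, by = period)
  times <- times[times < call_duration_s]
  if (mode == "random") {
    times <- sort(stats::runif(length(times), 0, call_duration_s))
  }
  glint_schedule(times, flutter_rate_hz, call_duration_s, mode)
}

#' @export
print.glint_schedule <- function(x, ...) {
  cat(sprintf("glint_schedule: %d %s glints, flutter %g Hz, call %g ms\n",
              length(x$sample_times), x$mode, x$flutter_rate_hz,
              1000 * x$call_duration_s))
  invisible(x)
}

# Fractional stroke-position coordinate for each sample time: one full ear
# stroke spans one call duration, positions 0 .. n_pos-1.
schedule_positions <- function(schedule, n_pos) {
  schedule$sample_times / schedule$call_duration_s * (n_pos - 1)
}

# Interpolate an n_dir x n_pos level matrix at fractional positions.
interp_positions <- function(m, x) {
  lo <- pmin(floor(x), ncol(m) - 1)
  w <- x - lo
  m[, lo + 1, drop = FALSE] * rep(1 - w, each = nrow(m)) +
    m[, pmin(lo + 2, ncol(m)), drop = FALSE] * rep(w, each = nrow(m))
}

#' Sample one template at the glint times
#'
#' @param levels a 2 x `n_pos` matrix (ears x stroke positions) of expected
#'   levels in dB, e.g. `templates$levels[i, , ]` for one direction.
#' @param schedule a `glint_schedule`.
#' @return a numeric vector of length `2k` (left-ear samples, then
#'   right-ear samples), obtained by linear interpolation between stroke
#'   positions.
#' @export
sample_template <- function(levels, schedule) {
  if (!inherits(schedule, "glint_schedule")) stopf("`schedule` must be a glint_schedule")
  levels <- rbind(levels)
  if (nrow(levels) != 2L) stopf("`levels` must be a 2 x n_pos matrix")
  x <- schedule_positions(schedule, ncol(levels))
  v <- interp_positions(levels, x)
  c(v[1, ], v[2, ])
}

#' Sample all templates at the glint times
#'
#' Vectorized form of [sample_template()] over a whole template set.
#'
#' @param templates a `binaural_templates` object.
#' @param schedule a `glint_schedule`.
#' @return an `n_dir` x `2k` matrix (left-ear columns then right-ear
#'   columns) with the schedule attached as attribute `"schedule"`.
#' @export
sample_templates <- function(templates, schedule) {
  n_dir <- dim(templates$levels)[1]
  x <- schedule_positions(schedule, templates$n_pos)
  s <- cbind(interp_positions(matrix(templates$levels[, 1L, ], nrow = n_dir), x),
             interp_positions(matrix(templates$levels[, 2L, ], nrow = n_dir), x))
  attr(s, "schedule") <- schedule
  attr(s, "k") <- length(x)
  s
}

# Full-template "sampling": all stroke positions of both ears concatenated,
# used by the unsampled (whole-echo) frequency channel.
full_templates <- function(templates) {
  n_dir <- dim(templates$levels)[1]
  s <- cbind(matrix(templates$levels[, 1L, ], nrow = n_dir),
             matrix(templates$levels[, 2L, ], nrow = n_dir))
  attr(s, "k") <- templates$n_pos
  s
}

#' Template dynamic range
#'
#' Max minus min expected level per template, in dB, over both ears and all
#' stroke positions.  High dynamic range makes a template resistant to
#' amplitude noise at the price of low sensitivity somewhere in the stroke.
#'
#' @param templates a `binaural_templates` object, or a single 2 x `n_pos`
#'   level matrix.
#' @return a numeric vector of per-template dynamic ranges (dB).
#' @export
template_dynamic_range <- function(templates) {
  if (inherits(templates, "binaural_templates")) {
    apply(templates$levels, 1, max) - apply(templates$levels, 1, min)
  } else {
    max(templates) - min(templates)
  }
}

#' Mean modulation spectrum of the templates
#'
#' Discrete magnitude spectrum of each ear's stroke sequence, averaged over
#' ears and directions, with the frequency axis in cycles per ear stroke.
#' The magnitudes use an energy-preserving one-sided convention: the summed
#' squared magnitudes over the returned bins equal the summed squared
#' samples of the sequence (Parseval).
#'
#' @param templates a `binaural_templates` object.
#' @return a data.frame with columns `cycles_per_stroke` (0, 1, ...,
#'   floor(n_pos/2)) and `mean_magnitude` (dB-domain amplitude units).
#' @export
template_spectrum <- function(templates) {
  n <- templates$n_pos
  n_dir <- dim(templates$levels)[1]
  # columns: one stroke sequence per (direction, ear)
  seqs <- cbind(t(matrix(templates$levels[, 1L, ], nrow = n_dir)),
                t(matrix(templates$levels[, 2L, ], nrow = n_dir)))
  pw <- Mod(stats::mvfft(seqs))^2 / n
  h <- n %/% 2
  one_sided <- pw[seq_len(h + 1), , drop = FALSE]
  for (kk in seq_len(h)) {
    mirror <- n - kk + 1                  # negative-frequency partner
    if (mirror > kk + 1) {
      one_sided[kk + 1, ] <- one_sided[kk + 1, ] + pw[mirror, ]
    }
  }
  data.frame(cycles_per_stroke = 0:h,
             mean_magnitude = rowMeans(sqrt(one_sided)))
}

#' Nyquist limit of glint sampling
#'
#' The highest template modulation frequency, in cycles per ear stroke, that
#' `k = flutter_rate * call_duration` glint samples can faithfully
#' reconstruct: `flutter_rate * call_duration / 2`.  A 100 Hz flutter in a
#' 50 ms call gives 5 glints and a limit of 2.5 cycles per stroke.
#'
#' @param flutter_rate_hz flutter rate in Hz (> 0).
#' @param call_duration_s call duration in seconds (> 0).
#' @return the Nyquist limit in cycles per ear stroke.
#' @export
nyquist_limit <- function(flutter_rate_hz, call_duration_s = 0.05) {
  if (any(flutter_rate_hz <= 0) || any(call_duration_s <= 0)) {
    stopf("`flutter_rate_hz` and `call_duration_s` must be positive")
  }
  flutter_rate_hz * call_duration_s / 2
}

#' Export templates to CSV
#'
#' Long-format export with columns `direction_id, azimuth_deg,
#' elevation_deg, ear, position_index, level_db`.
#'
#' @param templates a `binaural_templates` object.
#' @param path output file path.
#' @export
write_templates <- function(templates, path) {
  n_dir <- dim(templates$levels)[1]
  n_pos <- templates$n_pos
  g <- templates$grid
  out <- data.frame(
    direction_id   = rep(g$direction_id, times = 2L * n_pos),
    azimuth_deg    = rep(g$azimuth_deg, times = 2L * n_pos),
    elevation_deg  = rep(g$elevation_deg, times = 2L * n_pos),
    ear            = rep(rep(c("left", "right"), each = n_dir), times = n_pos),
    position_index = rep(seq_len(n_pos), each = 2L * n_dir),
    level_db       = as.vector(templates$levels)
  )
  data.table::fwrite(out, path)
  invisible(path)
}
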