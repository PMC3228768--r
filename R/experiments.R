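# Figure-level experiment drivers.
#
# Each driver takes an experiment_config, builds (or reuses) the synthetic
# model, runs the entropy engine and returns tidy tables.  Every driver is
# deterministic given (config, seed).

#' Experiment configuration
#'
#' Collects every tunable parameter of the simulation study.  The defaults
#' are the desk-scale study conditions: a 500-direction grid, five flutter
#' rates spanning 20-200 Hz, eight echo strengths spanning 0-70 dB, the
#' three reference noise channels and 20 Monte-Carlo realizations per cell.
#' The full-scale reference configuration uses `grid_size = 3252` and
#' `echo_strengths_db = seq(0, 70, 5)`.
#'
#' @param grid_size number of directions in the hypothesis grid.
#' @param flutter_rates_hz flutter rates to simulate (Hz).
#' @param echo_strengths_db true echo strengths; also the nuisance prior grid.
#' @param sigma_db named numeric vector of noise channels (dB).
#' @param rho_lr left/right correlation of simultaneous samples.
#' @param floor_db detection threshold (dB).
#' @param call_duration_s call duration in seconds.
#' @param realizations Monte-Carlo realizations per cell.
#' @param modes glint-spacing modes to simulate.
#' @param n_pos stroke positions per ear in the templates.
#' @param f_base_hz baseline flutter rate for differences and performance.
#' @param emission_beamwidth,ear_beamwidth,ear_boresight_az,ear_boresight_el
#'   synthetic beam geometry, see [default_ahrtf()].
#' @param arc_az_deg,arc_el_deg,az_convention pinna stroke arc, see
#'   [make_trajectory()].
#' @param map_sigma channel name used for entropy maps.
#' @param map_strength_db echo strength used for entropy maps (dB).
#' @param central_angle_deg off-axis angle bounding the "central" region in
#'   trade-off summaries.
#' @param source_ids optional subset of direction ids used as true sources
#'   (`NULL`: all).
#' @param seed root seed; every driver derives its streams from it.
#' @return an object of class `experiment_config` (a validated list).
#' @export
experiment_config <- function(grid_size = 500,
                              flutter_rates_hz = c(20, 60, 100, 150, 200),
                              echo_strengths_db = seq(0, 70, by = 10),
                              sigma_db = c(low = 1.5, mid = 3, high = 6),
                              rho_lr = 0.9,
                              floor_db = 0,
                              call_duration_s = 0.05,
                              realizations = 20,
                              modes = c("regular", "random"),
                              n_pos = 40,
                              f_base_hz = 200,
                              emission_beamwidth = 40,
                              ear_beamwidth = 45,
                              ear_boresight_az = 20,
                              ear_boresight_el = 10,
                              arc_az_deg = 15,
                              arc_el_deg = 15,
                              az_convention = "mirrored",
                              map_sigma = "low",
                              map_strength_db = 40,
                              central_angle_deg = 30,
                              source_ids = NULL,
                              seed = 20111201) {
  cfg <- list(grid_size = grid_size, flutter_rates_hz = flutter_rates_hz,
              echo_strengths_db = echo_strengths_db, sigma_db = sigma_db,
              rho_lr = rho_lr, floor_db = floor_db,
              call_duration_s = call_duration_s, realizations = realizations,
              modes = modes, n_pos = n_pos, f_base_hz = f_base_hz,
              emission_beamwidth = emission_beamwidth,
              ear_beamwidth = ear_beamwidth,
              ear_boresight_az = ear_boresight_az,
              ear_boresight_el = ear_boresight_el,
              arc_az_deg = arc_az_deg, arc_el_deg = arc_el_deg,
              az_convention = az_convention, map_sigma = map_sigma,
              map_strength_db = map_strength_db,
              central_angle_deg = central_angle_deg,
              source_ids = source_ids, seed = seed)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  check_number(cfg$grid_size, "grid_size", lower = 1)
  if (length(cfg$flutter_rates_hz) == 0 || any(cfg$flutter_rates_hz <= 0)) {
    stopf("`flutter_rates_hz` must be a non-empty vector of positive rates")
  }
  if (length(cfg$echo_strengths_db) == 0) {
    stopf("`echo_strengths_db` must be non-empty")
  }
  if (length(cfg$sigma_db) == 0 || any(cfg$sigma_db < 0)) {
    stopf("`sigma_db` must be non-negative")
  }
  if (is.null(names(cfg$sigma_db)) || any(names(cfg$sigma_db) == "")) {
    stopf("`sigma_db` channels must be named")
  }
  check_number(cfg$rho_lr, "rho_lr", lower = 0)
  if (cfg$rho_lr >= 1) stopf("`rho_lr` must be < 1")
  check_number(cfg$call_duration_s, "call_duration_s")
  if (cfg$call_duration_s <= 0) stopf("`call_duration_s` must be positive")
  check_number(cfg$realizations, "realizations", lower = 1)
  bad <- setdiff(cfg$modes, c("regular", "random"))
  if (length(bad)) stopf("unknown mode(s): %s", paste(bad, collapse = ", "))
  check_number(cfg$n_pos, "n_pos", lower = 1)
  check_number(cfg$f_base_hz, "f_base_hz")
  if (!cfg$map_sigma %in% names(cfg$sigma_db)) {
    stopf("`map_sigma` must name one of the sigma_db channels")
  }
  check_number(cfg$seed, "seed", lower = 0, upper = .Machine$integer.max)
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment_config:\n")
  cat(sprintf("  grid %d directions, %d stroke positions, call %g ms\n",
              x$grid_size, x$n_pos, 1000 * x$call_duration_s))
  cat(sprintf("  flutter %s Hz (baseline %g), strengths %g..%g dB (%d)\n",
              paste(x$flutter_rates_hz, collapse = "/"), x$f_base_hz,
              min(x$echo_strengths_db), max(x$echo_strengths_db),
              length(x$echo_strengths_db)))
  cat(sprintf("  noise channels [%s] = %s dB, rho %g, floor %g dB\n",
              paste(names(x$sigma_db), collapse = "/"),
              paste(x$sigma_db, collapse = "/"), x$rho_lr, x$floor_db))
  cat(sprintf("  %d realizations/cell, modes %s, seed %d\n",
              x$realizations, paste(x$modes, collapse = "/"), x$seed))
  invisible(x)
}

config_noise <- function(cfg, channel) {
  noise_spec(unname(cfg$sigma_db[[channel]]), cfg$rho_lr, cfg$floor_db)
}

config_prior <- function(cfg) {
  p <- structure(list(a_db = as.numeric(cfg$echo_strengths_db)),
                 class = "echo_strength_prior")
  p
}

#' Build the synthetic model a configuration describes
#'
#' Constructs the direction grid, the parametric emission/ear beams, the
#' pinna trajectories and the binaural templates.
#'
#' @param cfg an `experiment_config`.
#' @return a list with `grid`, `templates` and the `ahrtf` components.
#' @export
setup_experiment <- function(cfg) {
  grid <- make_direction_grid(cfg$grid_size)
  ah <- default_ahrtf(emission_beamwidth = cfg$emission_beamwidth,
                      ear_beamwidth = cfg$ear_beamwidth,
                      ear_boresight_az = cfg$ear_boresight_az,
                      ear_boresight_el = cfg$ear_boresight_el,
                      arc_az_deg = cfg$arc_az_deg,
                      arc_el_deg = cfg$arc_el_deg,
                      n_pos = cfg$n_pos,
                      az_convention = cfg$az_convention)
  templates <- build_templates(ah$emission, ah$ear_left, ah$ear_right,
                               ah$traj_left, ah$traj_right, grid)
  c(list(grid = grid, templates = templates), ah)
}

#' Entropy maps per flutter rate
#'
#' One azimuth-elevation entropy map per flutter rate at a fixed noise
#' channel and echo strength, with Lambert equal-area plotting coordinates.
#'
#' @param cfg an `experiment_config`.
#' @param setup optional result of [setup_experiment()] to reuse.
#' @return a list with the raw `surface` and the `maps` table
#'   (`direction_id, azimuth_deg, elevation_deg, x, y, flutter_hz,
#'   entropy_bits`).
#' @export
run_entropy_maps <- function(cfg, setup = NULL) {
  setup <- setup %||% setup_experiment(cfg)
  spec <- config_noise(cfg, cfg$map_sigma)
  prior <- config_prior(cfg)
  surf <- entropy_surface(setup$templates, cfg$flutter_rates_hz, spec,
                          prior, source_ids = cfg$source_ids,
                          realizations = cfg$realizations,
                          call_duration_s = cfg$call_duration_s,
                          mode = "regular", seed = cfg$seed)
  maps <- surf[surf$echo_strength_db == cfg$map_strength_db, ]
  if (nrow(maps) == 0) {
    stopf("`map_strength_db` (%g) is not among `echo_strengths_db`",
          cfg$map_strength_db)
  }
  xy <- lambert_project(maps$azimuth_deg, maps$elevation_deg)
  maps <- data.frame(direction_id = maps$direction_id,
                     azimuth_deg = maps$azimuth_deg,
                     elevation_deg = maps$elevation_deg,
                     x = xy$x, y = xy$y,
                     flutter_hz = maps$flutter_hz,
                     entropy_bits = maps$mean_entropy_bits)
  list(surface = surf, maps = maps)
}

#' Flutter sweep with baseline differences
#'
#' Runs the entropy surface for each configured noise channel and glint
#' mode and tabulates the direction-averaged entropy difference between
#' each flutter rate and the baseline rate.
#'
#' @param cfg an `experiment_config`.
#' @param setup optional result of [setup_experiment()].
#' @param channels channel names to sweep (default: all configured).
#' @return a list with `surfaces` (one per channel x mode) and
#'   `differences`, a table of `channel, mode, flutter_hz,
#'   echo_strength_db, mean_entropy_bits, delta_vs_base_bits`.
#' @export
run_flutter_sweep <- function(cfg, setup = NULL,
                              channels = names(cfg$sigma_db)) {
  if (!cfg$f_base_hz %in% cfg$flutter_rates_hz) {
    stopf("`f_base_hz` must be among `flutter_rates_hz`")
  }
  setup <- setup %||% setup_experiment(cfg)
  prior <- config_prior(cfg)
  surfaces <- list()
  diffs <- list()
  seeds <- derive_seeds(cfg$seed, length(channels) * length(cfg$modes))
  i <- 0L
  for (ch in channels) {
    for (mode in cfg$modes) {
      i <- i + 1L
      surf <- entropy_surface(setup$templates, cfg$flutter_rates_hz,
                              config_noise(cfg, ch), prior,
                              source_ids = cfg$source_ids,
                              realizations = cfg$realizations,
                              call_duration_s = cfg$call_duration_s,
                              mode = mode, seed = seeds[i])
      hbar <- stats::aggregate(mean_entropy_bits ~ flutter_hz + echo_strength_db,
                               data = surf, FUN = mean)
      base <- hbar[hbar$flutter_hz == cfg$f_base_hz,
                   c("echo_strength_db", "mean_entropy_bits")]
      names(base)[2] <- "base_bits"
      hbar <- merge(hbar, base, by = "echo_strength_db")
      hbar$delta_vs_base_bits <- hbar$mean_entropy_bits - hbar$base_bits
      hbar <- data.frame(channel = ch, mode = mode,
                         flutter_hz = hbar$flutter_hz,
                         echo_strength_db = hbar$echo_strength_db,
                         mean_entropy_bits = hbar$mean_entropy_bits,
                         delta_vs_base_bits = hbar$delta_vs_base_bits)
      key <- paste(ch, mode, sep = ".")
      surfaces[[key]] <- surf
      diffs[[key]] <- hbar
    }
  }
  differences <- do.call(rbind, diffs)
  rownames(differences) <- NULL
  differences <- differences[order(differences$channel, differences$mode,
                                   differences$flutter_hz,
                                   differences$echo_strength_db), ]
  list(surfaces = surfaces, differences = differences)
}

#' Two-channel comparison: sampled glints vs whole echo
#'
#' Channel (a) samples the templates at the dominant glints and enjoys the
#' low dominant-glint noise level; channel (b) uses the full templates at
#' every stroke position (no sampling) but suffers the high whole-echo
#' noise level.  The difference table reports (a) minus (b); channel (b)
#' does not depend on flutter rate and is computed once.
#'
#' @param cfg an `experiment_config`.
#' @param setup optional result of [setup_experiment()].
#' @param sampled_channel,unsampled_channel channel names for the two sides.
#' @return a list with `sampled`, `unsampled` (entropy surfaces) and
#'   `difference` (`flutter_hz, echo_strength_db, sampled_bits,
#'   unsampled_bits, difference_bits`).
#' @export
run_channel_comparison <- function(cfg, setup = NULL,
                                   sampled_channel = "low",
                                   unsampled_channel = "high") {
  setup <- setup %||% setup_experiment(cfg)
  prior <- config_prior(cfg)
  seeds <- derive_seeds(cfg$seed, 2)
  surf_a <- entropy_surface(setup$templates, cfg$flutter_rates_hz,
                            config_noise(cfg, sampled_channel), prior,
                            source_ids = cfg$source_ids,
                            realizations = cfg$realizations,
                            call_duration_s = cfg$call_duration_s,
                            mode = "regular", seed = seeds[1])
  surf_b <- entropy_surface(setup$templates, cfg$f_base_hz,
                            config_noise(cfg, unsampled_channel), prior,
                            source_ids = cfg$source_ids,
                            realizations = cfg$realizations,
                            call_duration_s = cfg$call_duration_s,
                            mode = "unsampled", seed = seeds[2])
  ha <- stats::aggregate(mean_entropy_bits ~ flutter_hz + echo_strength_db,
                         data = surf_a, FUN = mean)
  hb <- stats::aggregate(mean_entropy_bits ~ echo_strength_db,
                         data = surf_b, FUN = mean)
  names(ha)[3] <- "sampled_bits"
  names(hb)[2] <- "unsampled_bits"
  d <- merge(ha, hb, by = "echo_strength_db")
  d$difference_bits <- d$sampled_bits - d$unsampled_bits
  d <- d[order(d$flutter_hz, d$echo_strength_db),
         c("flutter_hz", "echo_strength_db", "sampled_bits",
           "unsampled_bits", "difference_bits")]
  rownames(d) <- NULL
  list(sampled = surf_a, unsampled = surf_b, difference = d)
}

#' Template diagnostics
#'
#' Per-template dynamic range (with histogram), the mean modulation
#' spectrum in cycles per ear stroke, and the Nyquist limit for each
#' configured flutter rate.
#'
#' @param cfg an `experiment_config`.
#' @param setup optional result of [setup_experiment()].
#' @return a list with `dynamic_range` (vector), `histogram`
#'   (`mid_db, count`), `spectrum` and `nyquist`
#'   (`flutter_hz, samples_per_ear, nyquist_cycles_per_stroke`).
#' @export
run_template_diagnostics <- function(cfg, setup = NULL) {
  setup <- setup %||% setup_experiment(cfg)
  dr <- template_dynamic_range(setup$templates)
  br <- pretty(c(0, dr), n = 20)
  hist <- graphics::hist(dr, breaks = br, plot = FALSE)
  list(
    dynamic_range = dr,
    histogram = data.frame(mid_db = hist$mids, count = hist$counts),
    spectrum = template_spectrum(setup$templates),
    nyquist = data.frame(
      flutter_hz = cfg$flutter_rates_hz,
      samples_per_ear = cfg$flutter_rates_hz * cfg$call_duration_s,
      nyquist_cycles_per_stroke = nyquist_limit(cfg$flutter_rates_hz,
                                                cfg$call_duration_s))
  )
}

#' Sensitivity-accuracy trade-off maps
#'
#' Entropy maps as a function of echo strength for two noise channels at
#' the baseline flutter rate, with a central-versus-peripheral contrast
#' summary.  The central region is the set of directions within
#' `central_angle_deg` of the midline axis.
#'
#' @param cfg an `experiment_config` with at least 3 echo strengths.
#' @param setup optional result of [setup_experiment()].
#' @param channels two channel names to contrast.
#' @param low_entropy_bits threshold defining the "low entropy" region
#'   whose area fraction is tracked against echo strength.
#' @return a list with `surfaces` and `summary`
#'   (`channel, echo_strength_db, central_bits, peripheral_bits,
#'   contrast_bits, low_entropy_area_frac`).
#' @export
run_tradeoff_maps <- function(cfg, setup = NULL,
                              channels = c("low", "high"),
                              low_entropy_bits = NULL) {
  if (length(cfg$echo_strengths_db) < 3) {
    stopf("trade-off maps need at least 3 echo strengths")
  }
  if (length(channels) < 2) stopf("trade-off maps need two channels")
  setup <- setup %||% setup_experiment(cfg)
  prior <- config_prior(cfg)
  low_entropy_bits <- low_entropy_bits %||% (log2(cfg$grid_size) / 2)
  central <- great_circle_distance(setup$grid$azimuth_deg,
                                   setup$grid$elevation_deg, 0, 0) <=
    cfg$central_angle_deg
  seeds <- derive_seeds(cfg$seed, length(channels))
  surfaces <- list()
  summaries <- list()
  for (i in seq_along(channels)) {
    ch <- channels[i]
    surf <- entropy_surface(setup$templates, cfg$f_base_hz,
                            config_noise(cfg, ch), prior,
                            source_ids = cfg$source_ids,
                            realizations = cfg$realizations,
                            call_duration_s = cfg$call_duration_s,
                            mode = "regular", seed = seeds[i])
    surfaces[[ch]] <- surf
    is_central <- central[surf$direction_id]
    agg <- function(sel) {
      stats::aggregate(mean_entropy_bits ~ echo_strength_db,
                       data = surf[sel, ], FUN = mean)$mean_entropy_bits
    }
    a_vals <- sort(unique(surf$echo_strength_db))
    low_frac <- vapply(a_vals, function(a) {
      mean(surf$mean_entropy_bits[surf$echo_strength_db == a] <
             low_entropy_bits)
    }, numeric(1))
    summaries[[ch]] <- data.frame(
      channel = ch, echo_strength_db = a_vals,
      central_bits = agg(is_central),
      peripheral_bits = agg(!is_central),
      contrast_bits = agg(is_central) - agg(!is_central),
      low_entropy_area_frac = low_frac)
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  list(surfaces = surfaces, summary = summary)
}
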