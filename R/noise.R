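# Within-echo amplitude noise model.
#
# Received levels are expressed in dB.  Noise is i.i.d. across glint
# samples, with simultaneous left/right samples sharing a high (but not
# perfect) correlation; the detection floor acts as an elementwise maximum
# operator on the expected level.  The covariance is block structured:
# sigma^2 on the diagonal, rho * sigma^2 between sample i of the left ear
# and sample i of the right ear, zero elsewhere.

#' Noise specification
#'
#' @param sigma_db per-sample amplitude standard deviation in dB (>= 0).
#'   The package's three reference channels are 1.5 dB (dominant-glint,
#'   low), 3 dB (intermediate) and 6 dB (whole-echo, high).
#' @param rho_lr correlation between simultaneous left/right samples, in
#'   `[0, 1)`.
#' @param floor_db detection threshold in dB; received levels below it are
#'   clipped up to it.  With the default 0 dB floor the echo strength reads
#'   as a signal-to-noise ratio.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_db, rho_lr = 0.9, floor_db = 0) {
  check_number(sigma_db, "sigma", lower = 0)
  check_number(rho_lr, "rho_lr", lower = 0)
  if (rho_lr >= 1) stopf("`rho_lr` must be < 1 (the covariance is singular at 1)")
  check_number(floor_db, "floor_db")
  structure(list(sigma_db = sigma_db, rho_lr = rho_lr, floor_db = floor_db),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("noise_spec: sigma %g dB, rho_lr %g, floor %g dB\n",
              x$sigma_db, x$rho_lr, x$floor_db))
  invisible(x)
}

#' Reference noise channels
#'
#' The three noise levels the simulations are run at: a low channel for the
#' amplitude-stable dominant glints, a high channel for frequency channels
#' stimulated over the whole echo, and an intermediate level between them.
#'
#' @param sigma_low_db,sigma_mid_db,sigma_high_db channel SDs in dB.
#' @param rho_lr,floor_db shared correlation and detection floor.
#' @return a named list of `noise_spec` objects (`low`, `mid`, `high`).
#' @export
default_noise_channels <- function(sigma_low_db = 1.5, sigma_mid_db = 3,
                                   sigma_high_db = 6, rho_lr = 0.9,
                                   floor_db = 0) {
  list(low  = noise_spec(sigma_low_db, rho_lr, floor_db),
       mid  = noise_spec(sigma_mid_db, rho_lr, floor_db),
       high = noise_spec(sigma_high_db, rho_lr, floor_db))
}

#' Build the 2k x 2k noise covariance matrix
#'
#' Rows/columns are ordered left-ear samples 1..k then right-ear samples
#' 1..k.  The matrix is `sigma^2` on the diagonal, `rho * sigma^2` between
#' simultaneous left/right samples, and zero elsewhere; it is positive
#' definite for `rho < 1`.
#'
#' @param k number of samples per ear (>= 1).
#' @param spec a `noise_spec`.
#' @return a 2k x 2k covariance matrix (dB^2).
#' @export
build_covariance <- function(k, spec) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stopf("`k` must be a single integer >= 1")
  }
  k <- as.integer(k)
  s2 <- spec$sigma_db^2
  sig <- diag(s2, 2L * k)
  idx <- cbind(seq_len(k), k + seq_len(k))
  sig[idx] <- spec$rho_lr * s2
  sig[idx[, 2:1, drop = FALSE]] <- spec$rho_lr * s2
  sig
}

# Draw n rows of correlated left/right noise (2k columns) using the
# closed-form Cholesky factor of the 2x2 left/right blocks.
sim_noise_rows <- function(n, k, spec) {
  z1 <- matrix(stats::rnorm(n * k), n, k)
  z2 <- matrix(stats::rnorm(n * k), n, k)
  cbind(spec$sigma_db * z1,
        spec$sigma_db * (spec$rho_lr * z1 + sqrt(1 - spec$rho_lr^2) * z2))
}

# Whiten rows of x (2k columns, left then right) under the standard block
# covariance; rowSums(whiten^2) is the Mahalanobis quadratic form.
whiten_pairs <- function(x, k, spec) {
  l <- x[, seq_len(k), drop = FALSE]
  r <- x[, k + seq_len(k), drop = FALSE]
  cbind(l / spec$sigma_db,
        (r - spec$rho_lr * l) / (spec$sigma_db * sqrt(1 - spec$rho_lr^2)))
}

# log det of the block covariance for k samples per ear
block_logdet <- function(k, spec) {
  2 * k * log(spec$sigma_db^2) + k * log(1 - spec$rho_lr^2)
}

#' Simulate a received measurement vector
#'
#' Adds echo strength and correlated Gaussian amplitude noise to a sampled
#' template and applies the detection floor: `values = pmax(floor,
#' template + A + noise)`.
#'
#' @param st sampled template values, a length-`2k` numeric vector (left
#'   samples then right samples), e.g. from [sample_template()].
#' @param a_db echo strength in dB (finite).
#' @param spec a `noise_spec`.
#' @param direction_id optional identifier of the true direction, carried
#'   through for bookkeeping.
#' @return an object of class `measurement` with elements `values`,
#'   `direction_id`, `a_db`.
#' @export
simulate_measurement <- function(st, a_db, spec, direction_id = NA_integer_) {
  check_number(a_db, "a_db")
  st <- as.numeric(st)
  if (length(st) %% 2L != 0L) stopf("`st` must have even length (2k)")
  k <- length(st) %/% 2L
  noise <- drop(sim_noise_rows(1L, k, spec))
  structure(list(values = pmax(spec$floor_db, st + a_db + noise),
                 direction_id = direction_id, a_db = a_db),
            class = "measurement")
}
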