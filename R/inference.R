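# Bayesian template matching and localization entropy.
#
# The likelihood of a received vector given a candidate direction and echo
# strength is a multivariate Gaussian about the floor-censored expected
# level max(floor, template + A).  Echo strength is unknown to the bat and
# marginalized over a uniform discrete prior; the posterior over the
# direction grid (uniform direction prior) yields the Shannon localization
# entropy in bits.  Average entropy per direction is estimated by Monte
# Carlo over schedule phase and noise.

#' Uniform echo-strength prior
#'
#' Discrete uniform prior over the nuisance echo strength, spanning all
#' strengths likely to be returned by prey (call level minus small-insect
#' target strength).
#'
#' @param a_min_db,a_max_db,step_db grid limits and spacing in dB.
#' @return an object of class `echo_strength_prior` with the grid in
#'   element `a_db`.
#' @export
echo_strength_prior <- function(a_min_db = 0, a_max_db = 70, step_db = 5) {
  check_number(a_min_db, "a_min_db")
  check_number(a_max_db, "a_max_db")
  check_number(step_db, "step_db")
  if (step_db <= 0) stopf("`step_db` must be positive")
  if (a_max_db < a_min_db) stopf("`a_max_db` must be >= `a_min_db`")
  structure(list(a_db = seq(a_min_db, a_max_db, by = step_db)),
            class = "echo_strength_prior")
}

#' @export
print.echo_strength_prior <- function(x, ...) {
  cat(sprintf("echo_strength_prior: uniform over %d strengths, %g..%g dB\n",
              length(x$a_db), min(x$a_db), max(x$a_db)))
  invisible(x)
}

#' Gaussian log likelihood with floor-censored mean
#'
#' Multivariate-normal log density of a measurement about the expected
#' received level `mu = pmax(floor, st + A)`, with covariance `sigma_mat`.
#'
#' @param values measurement values (length 2k).
#' @param st sampled template values (length 2k).
#' @param a_db echo strength hypothesis in dB.
#' @param sigma_mat 2k x 2k covariance matrix, e.g. [build_covariance()].
#' @param floor_db detection threshold in dB.
#' @return the log density.
#' @export
log_likelihood <- function(values, st, a_db, sigma_mat, floor_db = 0) {
  values <- as.numeric(values)
  st <- as.numeric(st)
  if (length(values) != length(st) || length(values) != nrow(sigma_mat)) {
    stopf("dimensions of `values`, `st` and `sigma_mat` must agree")
  }
  ch <- tryCatch(chol(sigma_mat), error = function(e) {
    stopf("covariance matrix is not positive definite (%s)",
          conditionMessage(e))
  })
  mu <- pmax(floor_db, st + a_db)
  w <- backsolve(ch, values - mu, transpose = TRUE)
  n <- length(values)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(w^2))
}

#' Marginal likelihood over echo strength
#'
#' Uniform-weight average of the likelihood over the echo-strength prior
#' grid, computed in log space.
#'
#' @inheritParams log_likelihood
#' @param prior an `echo_strength_prior`.
#' @param log if `TRUE` return the log marginal likelihood.
#' @return the (log) marginal likelihood.
#' @export
marginal_likelihood <- function(values, st, sigma_mat, prior, floor_db = 0,
                                log = FALSE) {
  if (!inherits(prior, "echo_strength_prior") || length(prior$a_db) == 0) {
    stopf("`prior` must be a non-empty echo_strength_prior")
  }
  ll <- vapply(prior$a_db, function(a) {
    log_likelihood(values, st, a, sigma_mat, floor_db)
  }, numeric(1))
  lm <- log_sum_exp(ll) - log(length(prior$a_db))
  if (log) lm else exp(lm)
}

#' Posterior over candidate directions
#'
#' Applies Bayes' theorem with a uniform prior over directions and the
#' echo strength marginalized out, and reports the Shannon entropy of the
#' posterior in bits.  If every direction's marginal log likelihood
#' underflows to `-Inf` the posterior falls back to uniform with a warning.
#'
#' @param values measurement values (length 2k).
#' @param sampled an `n_dir` x 2k matrix of sampled templates sharing the
#'   measurement's glint schedule, e.g. from [sample_templates()].
#' @param sigma_mat 2k x 2k covariance matrix.
#' @param prior an `echo_strength_prior`.
#' @param floor_db detection threshold in dB.
#' @return an object of class `posterior_result` with elements
#'   `probabilities` (summing to 1), `entropy_bits` and `log_marginals`.
#' @export
posterior <- function(values, sampled, sigma_mat, prior, floor_db = 0) {
  values <- as.numeric(values)
  sampled <- rbind(sampled)
  if (ncol(sampled) != length(values)) {
    stopf("`sampled` must have one column per measurement value")
  }
  ch <- tryCatch(chol(sigma_mat), error = function(e) {
    stopf("covariance matrix is not positive definite (%s)",
          conditionMessage(e))
  })
  n_dir <- nrow(sampled)
  n <- length(values)
  const <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))))
  ll <- matrix(NA_real_, n_dir, length(prior$a_db))
  for (ai in seq_along(prior$a_db)) {
    mu <- pmax(sampled + prior$a_db[ai], floor_db)  # matrix first: keep dim
    resid <- t(mu) - values                  # 2k x n_dir, column per direction
    w <- backsolve(ch, resid, transpose = TRUE)
    ll[, ai] <- const - 0.5 * colSums(w^2)
  }
  log_marg <- apply(ll, 1, log_sum_exp) - log(length(prior$a_db))
  total <- log_sum_exp(log_marg)
  if (!is.finite(total)) {
    warning("all direction likelihoods underflowed; returning uniform posterior")
    p <- rep(1 / n_dir, n_dir)
  } else {
    p <- exp(log_marg - total)
    p <- p / sum(p)
  }
  structure(list(probabilities = p, entropy_bits = entropy_bits(p),
                 log_marginals = log_marg),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("posterior_result: %d directions, entropy %.3f bits, MAP p = %.3g\n",
              length(x$probabilities), x$entropy_bits, max(x$probabilities)))
  invisible(x)
}

#' Monte-Carlo average localization entropy for one direction
#'
#' Mean posterior entropy over `realizations` independent draws of the
#' glint-schedule phase and the measurement noise for echoes from one true
#' direction at one echo strength.  This is the reference (slow, generic)
#' path; [entropy_surface()] computes the same quantity vectorized over
#' directions, strengths and flutter rates.
#'
#' @param templates a `binaural_templates` object.
#' @param direction_id row of the template grid the echo originates from.
#' @param flutter_rate_hz insect flutter rate in Hz.
#' @param spec a `noise_spec`.
#' @param a_db true echo strength in dB.
#' @param prior an `echo_strength_prior`.
#' @param realizations number of Monte-Carlo realizations (default 20).
#' @param call_duration_s call duration in seconds.
#' @param mode `"regular"` or `"random"` glint spacing.
#' @param redraw_schedule draw a fresh schedule phase per realization
#'   (default) or keep one schedule for all realizations.
#' @return mean entropy in bits.
#' @export
average_entropy <- function(templates, direction_id, flutter_rate_hz, spec,
                            a_db, prior = echo_strength_prior(),
                            realizations = 20, call_duration_s = 0.05,
                            mode = "regular", redraw_schedule = TRUE) {
  if (realizations < 1) stopf("`realizations` must be >= 1")
  sched <- make_glint_schedule(flutter_rate_hz, call_duration_s, mode)
  h <- numeric(realizations)
  for (r in seq_len(realizations)) {
    if (redraw_schedule && r > 1) {
      sched <- make_glint_schedule(flutter_rate_hz, call_duration_s, mode)
    }
    s <- sample_templates(templates, sched)
    k <- attr(s, "k")
    m <- simulate_measurement(s[direction_id, ], a_db, spec, direction_id)
    if (spec$sigma_db == 0) {
      d2 <- colSums((pmax(t(s) + a_db, spec$floor_db) - m$values)^2)
      hit <- d2 < 1e-18
      p <- hit / sum(hit)
      h[r] <- entropy_bits(p)
    } else {
      sig <- build_covariance(k, spec)
      h[r] <- posterior(m$values, s, sig, prior, spec$floor_db)$entropy_bits
    }
  }
  mean(h)
}

# ---------------------------------------------------------------------------
# Vectorized Monte-Carlo entropy engine.

# Group-sum matrix mapping (direction-major, strength-fastest) columns onto
# directions: column j of the result sums the n_a prior strengths of
# direction j.
prior_group_matrix <- function(n_dir, n_a) {
  Matrix::sparseMatrix(i = seq_len(n_dir * n_a),
                       j = rep(seq_len(n_dir), each = n_a),
                       x = 1, dims = c(n_dir * n_a, n_dir))
}

# Entropy rows for one block of measurements against a whitened template
# bank.  mw: block of whitened measurements; bw: whitened bank
# (n_dir*n_a rows, strength-fastest); qb: rowSums(bw^2); kd: group matrix.
block_entropy <- function(mw, bw, qb, kd) {
  ld <- mw %*% t(bw)
  ld <- sweep(ld, 2L, 0.5 * qb, `-`)         # log density + per-row constant
  mx <- ld[cbind(seq_len(nrow(ld)), max.col(ld, ties.method = "first"))]
  p <- exp(ld - mx)
  marg <- as.matrix(p %*% kd)
  s <- rowSums(marg)
  pl <- marg * log2(marg)
  pl[marg == 0] <- 0
  pmax(log2(s) - rowSums(pl) / s, 0)
}

# Noise-free entropy rows: posterior mass spread uniformly over exact
# matches.  The squared distance via the inner-product expansion suffers
# cancellation of order |x|^2 * eps, so the tolerance is row-relative.
block_entropy_exact <- function(m, b, kd, tol = 1e-9) {
  qm <- rowSums(m^2)
  qb <- rowSums(b^2)
  d2 <- outer(qm, qb, `+`) - 2 * (m %*% t(b))
  hit <- (d2 < tol * (1 + qm)) + 0
  marg <- as.matrix(hit %*% kd)
  s <- rowSums(marg)
  pl <- marg * log2(marg)
  pl[marg == 0] <- 0
  pmax(log2(s) - rowSums(pl) / s, 0)
}

#' Monte-Carlo localization entropy surface
#'
#' For every combination of true source direction, flutter rate and true
#' echo strength, estimates the mean posterior entropy over `realizations`
#' independent draws of the glint-schedule phase and the measurement noise.
#' The computation is vectorized: within one realization all source
#' directions and strengths share the drawn schedule, which leaves the
#' per-cell Monte-Carlo estimate unbiased while allowing the likelihood
#' evaluations to run as dense matrix products.
#'
#' In `"unsampled"` mode the whole-echo channel is modelled: templates are
#' used at all stroke positions (no glint sampling, so the result does not
#' depend on flutter rate) and the covariance block structure extends to
#' `2 * n_pos`.
#'
#' @param templates a `binaural_templates` object.
#' @param flutter_rates_hz numeric vector of flutter rates (Hz).
#' @param spec a `noise_spec`.
#' @param prior an `echo_strength_prior`; its grid doubles as the set of
#'   true echo strengths evaluated.
#' @param source_ids direction ids used as true sources (default: the whole
#'   grid).  Posteriors are always computed over the whole grid.
#' @param realizations Monte-Carlo realizations per cell (default 20).
#' @param call_duration_s call duration in seconds.
#' @param mode `"regular"`, `"random"` or `"unsampled"`.
#' @param seed optional integer seed making the surface reproducible.
#' @param block_rows measurement rows per processing block (memory knob).
#' @return an `entropy_surface`: a data.frame with columns `direction_id`,
#'   `azimuth_deg`, `elevation_deg`, `flutter_hz`, `echo_strength_db`,
#'   `sigma_db`, `mode`, `mean_entropy_bits`, `n_realizations`.
#' @export
entropy_surface <- function(templates, flutter_rates_hz, spec,
                            prior = echo_strength_prior(),
                            source_ids = NULL, realizations = 20,
                            call_duration_s = 0.05,
                            mode = c("regular", "random", "unsampled"),
                            seed = NULL, block_rows = 2048L) {
  mode <- match.arg(mode)
  if (realizations < 1) stopf("`realizations` must be >= 1")
  if (length(flutter_rates_hz) == 0) stopf("need at least one flutter rate")
  if (!is.null(seed)) set.seed(seed)
  grid <- templates$grid
  n_dir <- nrow(grid)
  src <- source_ids %||% grid$direction_id
  n_src <- length(src)
  a <- prior$a_db
  n_a <- length(a)
  kd <- prior_group_matrix(n_dir, n_a)
  n_f <- length(flutter_rates_hz)
  seeds <- sample.int(.Machine$integer.max, n_f * realizations)

  h_sum <- array(0, c(n_a, n_src, n_f))
  full_s <- if (mode == "unsampled") full_templates(templates) else NULL

  for (fi in seq_len(n_f)) {
    for (r in seq_len(realizations)) {
      set.seed(seeds[(fi - 1L) * realizations + r])
      if (mode == "unsampled") {
        s <- full_s
      } else {
        sched <- make_glint_schedule(flutter_rates_hz[fi], call_duration_s,
                                     mode)
        s <- sample_templates(templates, sched)
      }
      k <- attr(s, "k")
      # template bank over (direction, prior strength), strength-fastest;
      # n_dir * n_a rows is a multiple of n_a, so the strength vector
      # recycles along rows
      bank <- s[rep(seq_len(n_dir), each = n_a), , drop = FALSE] + a
      bank <- pmax(bank, spec$floor_db)
      # measurements over (source, true strength), strength-fastest
      m0 <- s[src, , drop = FALSE][rep(seq_len(n_src), each = n_a), ,
                                   drop = FALSE] + a
      if (spec$sigma_db == 0) {
        m <- pmax(m0, spec$floor_db)
        h_rows <- numeric(nrow(m))
        idx <- seq_len(nrow(m))
        for (blk in split(idx, ceiling(idx / block_rows))) {
          h_rows[blk] <- block_entropy_exact(m[blk, , drop = FALSE], bank, kd)
        }
      } else {
        m <- pmax(m0 + sim_noise_rows(nrow(m0), k, spec), spec$floor_db)
        bw <- whiten_pairs(bank, k, spec)
        qb <- rowSums(bw^2)
        mw <- whiten_pairs(m, k, spec)
        h_rows <- numeric(nrow(mw))
        idx <- seq_len(nrow(mw))
        for (blk in split(idx, ceiling(idx / block_rows))) {
          h_rows[blk] <- block_entropy(mw[blk, , drop = FALSE], bw, qb, kd)
        }
      }
      h_sum[, , fi] <- h_sum[, , fi] + matrix(h_rows, n_a, n_src)
    }
  }

  out <- data.frame(
    direction_id     = rep(rep(src, each = n_a), times = n_f),
    azimuth_deg      = rep(rep(grid$azimuth_deg[src], each = n_a), times = n_f),
    elevation_deg    = rep(rep(grid$elevation_deg[src], each = n_a), times = n_f),
    flutter_hz       = rep(flutter_rates_hz, each = n_a * n_src),
    echo_strength_db = rep(a, times = n_src * n_f),
    sigma_db         = spec$sigma_db,
    mode             = mode,
    mean_entropy_bits = as.vector(h_sum) / realizations,
    n_realizations   = realizations
  )
  attr(out, "n_templates") <- n_dir
  class(out) <- c("entropy_surface", "data.frame")
  out
}

#' @export
print.entropy_surface <- function(x, ...) {
  cat(sprintf(
    "entropy_surface: %d cells (%d directions x %d strengths x %d rates), %s mode\n",
    nrow(x), length(unique(x$direction_id)),
    length(unique(x$echo_strength_db)), length(unique(x$flutter_hz)),
    unique(x$mode)[1]))
  cat(sprintf("  mean entropy %.2f bits (sigma %g dB)\n",
              mean(x$mean_entropy_bits), unique(x$sigma_db)[1]))
  invisible(x)
}

#' Normalized performance versus flutter rate
#'
#' Summarizes an entropy surface as the percentage of the information
#' transferred at a baseline flutter rate (200 Hz in the reference
#' configuration): with `Hmax = log2(n_templates)` and `H(f, A)` the mean
#' entropy over directions,
#' `P(f) = 100 * sum_A (Hmax - H(f, A)) / sum_A (Hmax - H(f_base, A))`,
#' so `P(f_base) = 100` by construction.  The alternative
#' `method = "entropy"` reports the pure entropy ratio
#' `100 * sum_A H(f_base, A) / sum_A H(f, A)`.
#'
#' @param surface an `entropy_surface` (any number of directions; they are
#'   averaged out).
#' @param f_base_hz baseline flutter rate; must be present in the surface.
#' @param h_max_bits chance-level entropy; defaults to `log2(n_templates)`
#'   recorded on the surface.
#' @param method `"information"` (default) or `"entropy"`.
#' @return a data.frame with columns `flutter_hz` and `performance_pct`.
#' @export
performance_curve <- function(surface, f_base_hz = 200, h_max_bits = NULL,
                              method = c("information", "entropy")) {
  method <- match.arg(method)
  if (!f_base_hz %in% surface$flutter_hz) {
    stopf("baseline flutter rate %g Hz is not in the surface", f_base_hz)
  }
  h_max_bits <- h_max_bits %||% log2(attr(surface, "n_templates"))
  if (is.null(h_max_bits) || !is.finite(h_max_bits)) {
    stopf("`h_max_bits` must be supplied when the surface lacks an n_templates attribute")
  }
  hbar <- stats::aggregate(mean_entropy_bits ~ flutter_hz + echo_strength_db,
                           data = surface, FUN = mean)
  agg <- stats::aggregate(mean_entropy_bits ~ flutter_hz, data = hbar,
                          FUN = sum)
  n_a <- length(unique(hbar$echo_strength_db))
  base_sum <- agg$mean_entropy_bits[agg$flutter_hz == f_base_hz]
  if (method == "information") {
    denom <- n_a * h_max_bits - base_sum
    if (denom <= 0) {
      stopf("degenerate configuration: baseline carries no information")
    }
    perf <- 100 * (n_a * h_max_bits - agg$mean_entropy_bits) / denom
  } else {
    if (any(agg$mean_entropy_bits <= 0)) {
      stopf("degenerate configuration: zero entropy in the surface")
    }
    perf <- 100 * base_sum / agg$mean_entropy_bits
  }
  data.frame(flutter_hz = agg$flutter_hz, performance_pct = perf)
}
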