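test_that("the log likelihood is a censored-mean Gaussian density", {
  spec <- noise_spec(1, rho_lr = 0)
  sig <- build_covariance(1, spec)
  st <- c(2, 2)

  # at the mode the density equals the Gaussian normalizer
  mu <- pmax(0, st + 10)
  expect_equal(log_likelihood(mu, st, 10, sig), -log(2 * pi))

  # unit residual in one coordinate costs exactly 1/2
  expect_equal(log_likelihood(mu + c(1, 0), st, 10, sig), -log(2 * pi) - 0.5)

  # random small cases against the library-free quadratic-form oracle
  set.seed(21)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    spec <- noise_spec(runif(1, 0.5, 3), rho_lr = runif(1, 0, 0.95),
                       floor_db = runif(1, -5, 5))
    sig <- build_covariance(k, spec)
    st <- rnorm(2 * k, sd = 5)
    a <- runif(1, -10, 40)
    x <- rnorm(2 * k, mean = st + a, sd = 2)
    expect_equal(
      log_likelihood(x, st, a, sig, spec$floor_db),
      oracle_mvn_logpdf(x, pmax(spec$floor_db, st + a), sig),
      tolerance = 1e-10)
  }

  expect_error(log_likelihood(1:4, 1:2, 0, diag(2)), "agree")
  expect_error(log_likelihood(1:2, 1:2, 0, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("the marginal likelihood averages over the echo-strength prior", {
  spec <- noise_spec(1, rho_lr = 0.3)
  sig <- build_covariance(2, spec)
  st <- c(3, -1, 2, 0)

  # degenerate single-point prior
  p1 <- structure(list(a_db = 25), class = "echo_strength_prior")
  x <- st + 25 + c(0.3, -0.2, 0.1, 0)
  expect_equal(marginal_likelihood(x, st, sig, p1),
               exp(log_likelihood(x, st, 25, sig)), tolerance = 1e-12)

  # brute-force Riemann-sum oracle over the prior grid
  pr <- echo_strength_prior(10, 40, 5)
  brute <- mean(vapply(pr$a_db, function(a) {
    exp(oracle_mvn_logpdf(x, pmax(0, st + a), sig))
  }, numeric(1)))
  expect_equal(marginal_likelihood(x, st, sig, pr), brute,
               tolerance = 1e-12)

  # with small noise the likelihood peaks at the true strength
  spec_small <- noise_spec(0.3, rho_lr = 0)
  sig_small <- build_covariance(2, spec_small)
  scan <- vapply(pr$a_db, function(a) {
    log_likelihood(st + 25, st, a, sig_small)
  }, numeric(1))
  expect_equal(pr$a_db[which.max(scan)], 25)

  expect_error(marginal_likelihood(x, st, sig, list()), "prior")
})

test_that("the posterior identifies noiseless sources and degrades to uniform", {
  m <- tiny_model(n_dir = 25, n_pos = 12)
  set.seed(2)
  sch <- make_glint_schedule(100)
  s <- sample_templates(m$templates, sch)
  pr <- echo_strength_prior(0, 70, 5)

  # tiny noise, noiseless measurement: all mass on the true direction
  spec <- noise_spec(1e-3, rho_lr = 0)
  sig <- build_covariance(attr(s, "k"), spec)
  truth <- 17
  x <- pmax(0, s[truth, ] + 40)
  po <- posterior(x, s, sig, pr)
  expect_equal(which.max(po$probabilities), truth)
  expect_lt(po$entropy_bits, 1e-6)

  # identical templates: uniform posterior at chance entropy
  s0 <- matrix(0, 25, ncol(s))
  sig1 <- build_covariance(attr(s, "k"), noise_spec(1))
  po0 <- posterior(rep(40, ncol(s)), s0, sig1, pr)
  expect_equal(po0$probabilities, rep(1 / 25, 25))
  expect_equal(po0$entropy_bits, log2(25))

  # posterior normalization and entropy bounds on random draws
  spec <- noise_spec(2, rho_lr = 0.9)
  sig <- build_covariance(attr(s, "k"), spec)
  set.seed(31)
  for (i in 1:10) {
    mm <- simulate_measurement(s[sample(25, 1), ], runif(1, 0, 70), spec)
    po <- posterior(mm$values, s, sig, pr)
    expect_equal(sum(po$probabilities), 1, tolerance = 1e-9)
    expect_true(all(po$probabilities >= 0))
    expect_gte(po$entropy_bits, 0)
    expect_lte(po$entropy_bits, log2(25) + 1e-12)
  }
})

test_that("average entropy is zero without noise and reproducible when seeded", {
  m <- tiny_model(n_dir = 20, n_pos = 10)
  spec0 <- noise_spec(0)
  set.seed(4)
  h <- average_entropy(m$templates, 5, 100, spec0, 40, realizations = 3)
  expect_equal(h, 0)

  spec <- noise_spec(1.5)
  set.seed(99)
  h1 <- average_entropy(m$templates, 5, 60, spec, 20, realizations = 1)
  set.seed(99)
  h2 <- average_entropy(m$templates, 5, 60, spec, 20, realizations = 1)
  expect_identical(h1, h2)
  expect_gte(h1, 0)
})

test_that("the vectorized engine agrees with the reference per-cell path", {
  m <- tiny_model(n_dir = 30, n_pos = 10)
  spec <- noise_spec(2.5, rho_lr = 0.9)
  pr <- echo_strength_prior(20, 40, 10)

  surf <- entropy_surface(m$templates, 100, spec, pr,
                          realizations = 60, seed = 77)
  cell <- surf[surf$direction_id == 12 & surf$echo_strength_db == 30, ]

  set.seed(78)
  hs <- vapply(1:60, function(i) {
    average_entropy(m$templates, 12, 100, spec, 30, pr, realizations = 1)
  }, numeric(1))

  # the two routes share no code path beyond the template build; they must
  # agree within Monte-Carlo error
  se <- sqrt(stats::var(hs) / 60) + 0.02
  expect_lt(abs(cell$mean_entropy_bits - mean(hs)), 4 * se)
})

test_that("entropy surfaces are deterministic given a seed and bounded by chance", {
  m <- tiny_model(n_dir = 20, n_pos = 10)
  spec <- noise_spec(1.5)
  pr <- echo_strength_prior(0, 60, 20)
  s1 <- entropy_surface(m$templates, c(60, 200), spec, pr,
                        realizations = 3, seed = 10)
  s2 <- entropy_surface(m$templates, c(60, 200), spec, pr,
                        realizations = 3, seed = 10)
  expect_identical(s1, s2)
  expect_true(all(s1$mean_entropy_bits >= 0))
  expect_true(all(s1$mean_entropy_bits <= log2(20)))

  # noise-free surface is identically zero (distinct templates)
  s0 <- entropy_surface(m$templates, 100, noise_spec(0), pr,
                        realizations = 2, seed = 1)
  expect_equal(max(s0$mean_entropy_bits), 0)

  # source subsetting restricts rows but not the hypothesis space
  s3 <- entropy_surface(m$templates, 100, spec, pr, source_ids = c(3, 9),
                        realizations = 2, seed = 5)
  expect_equal(sort(unique(s3$direction_id)), c(3, 9))
})

test_that("the performance curve normalizes to 100% at the baseline", {
  # hand-built 2-flutter, 2-strength surface; Hmax = log2(4) = 2
  surf <- data.frame(
    direction_id = 1, azimuth_deg = 0, elevation_deg = 0,
    flutter_hz = rep(c(100, 200), each = 2),
    echo_strength_db = rep(c(10, 20), 2),
    sigma_db = 1.5, mode = "regular",
    mean_entropy_bits = c(1.0, 0.5, 0.6, 0.2),
    n_realizations = 1)
  attr(surf, "n_templates") <- 4
  class(surf) <- c("entropy_surface", "data.frame")

  p <- performance_curve(surf, 200)
  expect_equal(p$performance_pct[p$flutter_hz == 200], 100)
  # ((2-1) + (2-0.5)) / ((2-0.6) + (2-0.2)) = 2.5 / 3.2
  expect_equal(p$performance_pct[p$flutter_hz == 100], 100 * 2.5 / 3.2)

  # constant surface: performance 100% everywhere
  surf2 <- surf
  surf2$mean_entropy_bits <- 1.2
  attr(surf2, "n_templates") <- 4
  p2 <- performance_curve(surf2, 200)
  expect_equal(p2$performance_pct, c(100, 100))

  # entropy-ratio variant also pins the baseline at 100%
  p3 <- performance_curve(surf, 200, method = "entropy")
  expect_equal(p3$performance_pct[p3$flutter_hz == 200], 100)

  expect_error(performance_curve(surf, 150), "not in the surface")
})
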