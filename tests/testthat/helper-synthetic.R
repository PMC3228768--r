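# Small synthetic models shared across tests.  Everything is generated in
# code; sizes are kept small so individual tests stay fast.

tiny_model <- function(n_dir = 40, n_pos = 20, ear_beamwidth = 45,
                       emission_beamwidth = 40) {
  grid <- make_direction_grid(n_dir)
  ah <- default_ahrtf(emission_beamwidth = emission_beamwidth,
                      ear_beamwidth = ear_beamwidth, n_pos = n_pos)
  templates <- build_templates(ah$emission, ah$ear_left, ah$ear_right,
                               ah$traj_left, ah$traj_right, grid)
  c(list(grid = grid, templates = templates), ah)
}

# Constant (omnidirectional) gain field: makes all templates identical.
flat_pattern <- function() {
  directivity_pattern(function(u) rep(0, nrow(u)), label = "flat")
}

# Generic multivariate-normal log density via explicit matrix inversion;
# independent of the package's Cholesky/whitening path.
oracle_mvn_logpdf <- function(x, mu, sigma_mat) {
  n <- length(x)
  r <- x - mu
  logdet <- as.numeric(determinant(sigma_mat, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + logdet + drop(t(r) %*% solve(sigma_mat) %*% r))
}

# Shoelace area of a closed polygon given vertex coordinates.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Mean great-circle spacing CV of a grid (equal-area quality measure).
spacing_cv <- function(grid) {
  sp <- glintloc:::grid_nn_spacing(grid)
  stats::sd(sp) / mean(sp)
}
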