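# shared fixtures: all synthetic, built in code at test time

sim_measurement_table <- function(n = 20, seed = 1, ...) {
  generate_sites(generator_config(n_sites = n, ...), seed = seed)$table
}

sim_site_means <- function(n = 20, seed = 1, ...) {
  aggregate_site_means(sim_measurement_table(n, seed, ...))
}

# exact, noise-free optimality world: one measurement per site so the
# kinetics round trip is lossless
exact_optimality_sim <- function(n = 100, seed = 1, ...) {
  generate_sites(generator_config(n_sites = n, mode = "optimality_truth",
                                  obs_noise_sd = 0, meas_noise_sd = 0,
                                  measurements_per_site = 1, ...),
                 seed = seed)
}

# brute-force maximization of the net-gain objective over a Jmax grid;
# independent oracle for the optimality closed form
grid_vcmax_oracle <- function(t_g, par, vpd, ca, elevation, cost = 0.053,
                              pp = optimality_params(), n_grid = 20000) {
  opt <- optimal_vcmax(t_g, par, vpd, ca, elevation, cost, pp)
  theta <- pp$theta
  amp <- pp$phi0 * par
  m <- opt$m; mc <- opt$mc
  obj <- function(jm) {
    J <- ((amp + jm) - sqrt((amp + jm)^2 - 4 * theta * amp * jm)) / (2 * theta)
    m * J / 4 - cost * jm
  }
  g <- seq(1e-3, 5 * opt$jmax, length.out = n_grid)
  jopt <- g[which.max(obj(g))]
  J <- ((amp + jopt) - sqrt((amp + jopt)^2 - 4 * theta * amp * jopt)) / (2 * theta)
  list(jmax = jopt, vcmax = (m * J / 4) / mc, closed = opt)
}

# brute-force 1-D star discrepancy
star_discrepancy_1d <- function(x) {
  n <- length(x)
  xs <- sort(x)
  max(pmax(abs(xs - (seq_len(n) - 1) / n), abs(xs - seq_len(n) / n)))
}
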