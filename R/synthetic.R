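# Synthetic site-data generator: correlated climate/edaphic/trait covariates
# from a Gaussian copula (latent-factor loadings guarantee a valid
# correlation structure), site-level replicates with measurement noise, and
# two generative modes with fully known ground truth -- an empirical linear
# regression for Vcmax25, or the optimality model with a covariate-driven
# unit cost.

# marginal specs: type in {normal, lognormal, uniform}; lognormal given by
# (meanlog, sdlog), uniform by (min, max)
.default_marginals <- function() list(
  t_g           = list(type = "normal",    mean = 15,  sd = 6),
  vpd           = list(type = "lognormal", meanlog = log(1.0),  sdlog = 0.40),
  par           = list(type = "lognormal", meanlog = log(800),  sdlog = 0.30),
  ca            = list(type = "normal",    mean = 400, sd = 8),
  elevation     = list(type = "lognormal", meanlog = log(400),  sdlog = 0.90),
  precipitation = list(type = "lognormal", meanlog = log(1000), sdlog = 0.50),
  soil_ph       = list(type = "uniform",   min = 4,   max = 8.5),
  soil_c        = list(type = "lognormal", meanlog = log(30),   sdlog = 0.50),
  soil_n        = list(type = "lognormal", meanlog = log(2.5),  sdlog = 0.45),
  soil_cn       = list(type = "normal",    mean = 12,  sd = 2.5),
  alpha_pt      = list(type = "uniform",   min = 0.4, max = 1.26),
  cec           = list(type = "lognormal", meanlog = log(20),   sdlog = 0.45),
  silt          = list(type = "uniform",   min = 10,  max = 60),
  clay          = list(type = "uniform",   min = 5,   max = 45),
  bulk_density  = list(type = "normal",    mean = 1.3, sd = 0.15),
  lma           = list(type = "lognormal", meanlog = log(100),  sdlog = 0.35),
  na            = list(type = "lognormal", meanlog = log(1.8),  sdlog = 0.30)
)

# latent-factor loadings (rows = variables, cols = aridity, fertility,
# altitude factors); implied latent correlation is W W' + diag(1 - |w|^2),
# positive semi-definite by construction.
.default_loadings <- function() {
  vars <- names(.default_marginals())
  W <- matrix(0, length(vars), 3, dimnames = list(vars, c("arid", "fert", "alt")))
  W["t_g", ]           <- c(0.55, 0, -0.45)
  W["vpd", ]           <- c(0.70, 0, 0)
  W["par", ]           <- c(0.50, 0, 0.20)
  W["ca", ]            <- c(0, 0, -0.20)
  W["elevation", ]     <- c(0, 0, 0.85)
  W["precipitation", ] <- c(-0.65, 0.20, 0)
  W["soil_ph", ]       <- c(0.45, -0.30, 0)
  W["soil_c", ]        <- c(-0.30, 0.65, 0)
  W["soil_n", ]        <- c(-0.25, 0.70, 0)
  W["soil_cn", ]       <- c(0, -0.40, 0.15)
  W["alpha_pt", ]      <- c(-0.70, 0.10, 0)
  W["cec", ]           <- c(0, 0.55, 0)
  W["silt", ]          <- c(-0.15, 0.30, 0)
  W["clay", ]          <- c(0.10, 0.25, 0)
  W["bulk_density", ]  <- c(0.20, -0.45, 0)
  W["lma", ]           <- c(0.45, -0.15, 0.25)
  W["na", ]            <- c(0.35, 0.30, 0.15)
  W
}

.marginal_moments <- function(mg) {
  switch(mg$type,
         normal = c(mean = mg$mean, sd = mg$sd),
         lognormal = {
           m <- exp(mg$meanlog + mg$sdlog^2 / 2)
           s <- m * sqrt(exp(mg$sdlog^2) - 1)
           c(mean = m, sd = s)
         },
         uniform = c(mean = (mg$min + mg$max) / 2,
                     sd = (mg$max - mg$min) / sqrt(12)))
}

.quantile_transform <- function(z, mg) {
  switch(mg$type,
         normal = mg$mean + mg$sd * z,
         lognormal = exp(mg$meanlog + mg$sdlog * z),
         uniform = mg$min + (mg$max - mg$min) * stats::pnorm(z))
}

#' Synthetic-data generator configuration
#'
#' Defines the study conditions the generator emulates: number of sites,
#' replicate measurements per site, the covariate marginals and latent-factor
#' correlation structure, the ground-truth mode, effect sizes and noise
#' levels. The default regression truth carries the qualitative effect
#' pattern of the importance analysis (positive leaf N, soil pH and
#' precipitation, negative VPD and elevation effects on Vcmax25).
#'
#' @param n_sites number of sites.
#' @param measurements_per_site replicate leaf measurements per site.
#' @param mode `"regression_truth"` (linear Vcmax25 model) or
#'   `"optimality_truth"` (optimality model with covariate-driven cost).
#' @param gamma named coefficients of the Vcmax25 regression truth on
#'   standardized covariates (umol m-2 s-1 per SD); `gamma0` its intercept.
#' @param site_noise_sd SD of additive site-level noise on Vcmax25
#'   (regression mode), umol m-2 s-1.
#' @param obs_noise_sd SD of multiplicative lognormal observation noise
#'   applied to Vcmax in optimality mode (e.g. 0.05 = 5 percent noise).
#' @param meas_noise_sd SD of multiplicative lognormal replicate-level
#'   measurement noise.
#' @param cost_truth a [cost_model()] generating site costs in optimality
#'   mode (standardized-covariate scale; population means/SDs are filled in
#'   by the generator).
#' @param t_meas_offset,t_meas_jitter_sd leaf measurement temperature is
#'   `t_g + offset + N(0, jitter_sd)`, degrees C.
#' @param marginals,loadings covariate marginal specs and latent-factor
#'   loadings (see package defaults).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_sites = 200, measurements_per_site = 3,
                             mode = c("regression_truth", "optimality_truth"),
                             gamma = c(na = 10, vpd = -6, soil_ph = 5,
                                       precipitation = 4, elevation = -5),
                             gamma0 = 60,
                             site_noise_sd = 8, obs_noise_sd = 0.05,
                             meas_noise_sd = 0.05,
                             cost_truth = cost_model(
                               scenario = "edaphic", beta0 = 0.053,
                               betas = c(soil_n = -0.005, soil_ph = -0.004,
                                         cec = -0.0025, soil_cn = 0.0025)),
                             t_meas_offset = 2, t_meas_jitter_sd = 3,
                             marginals = .default_marginals(),
                             loadings = .default_loadings()) {
  mode <- match.arg(mode)
  stopifnot(n_sites >= 2, measurements_per_site >= 1,
            site_noise_sd >= 0, obs_noise_sd >= 0, meas_noise_sd >= 0)
  if (any(rowSums(loadings^2) > 1))
    stop("factor loadings imply residual variance < 0", call. = FALSE)
  structure(list(n_sites = n_sites,
                 measurements_per_site = measurements_per_site,
                 mode = mode, gamma = gamma, gamma0 = gamma0,
                 site_noise_sd = site_noise_sd, obs_noise_sd = obs_noise_sd,
                 meas_noise_sd = meas_noise_sd, cost_truth = cost_truth,
                 t_meas_offset = t_meas_offset,
                 t_meas_jitter_sd = t_meas_jitter_sd,
                 marginals = marginals, loadings = loadings),
            class = "generator_config")
}

#' Latent correlation matrix implied by a generator configuration
#'
#' @param config a [generator_config()].
#' @return Correlation matrix of the latent Gaussian covariates.
#' @export
implied_correlation <- function(config) {
  W <- config$loadings
  R <- W %*% t(W)
  diag(R) <- 1
  R
}

.draw_covariates <- function(config, seed) {
  rs <- .local_rng(seed)
  n <- config$n_sites
  W <- config$loadings
  vars <- rownames(W)
  Fmat <- matrix(rs$rnorm(n * ncol(W)), n, ncol(W))
  resid_sd <- sqrt(pmax(1 - rowSums(W^2), 0))
  E <- matrix(rs$rnorm(n * length(vars)), n, length(vars))
  Z <- Fmat %*% t(W) + sweep(E, 2, resid_sd, "*")
  colnames(Z) <- vars
  X <- as.data.frame(lapply(vars, function(v)
    .quantile_transform(Z[, v], config$marginals[[v]])))
  names(X) <- vars
  X$sand <- pmax(100 - X$silt - X$clay, 0)
  list(X = X, Z = Z)
}

#' Generate a synthetic site table with known ground truth
#'
#' Draws correlated covariates from the configured Gaussian copula, builds
#' true site Vcmax25 either from the linear regression truth or from the
#' optimality model with a covariate-driven unit cost, back-converts to
#' measurement temperature through the peaked Arrhenius kinetics, and adds
#' replicate-level measurement noise. In optimality mode, configurations
#' whose cost model is infeasible for more than 1 percent of sites are
#' regenerated with halved coefficients (with a warning).
#'
#' @param config a [generator_config()].
#' @param seed integer seed; fixed seeds give bit-identical tables.
#' @param kinetics a [kinetics_params()] object.
#' @param params an [optimality_params()] object.
#' @return List with `table` (measurement-level `site_table`) and `truth`
#'   (one row per site: true Vcmax25, Vcmax_Tg, site cost; attributes
#'   `gamma_std`, `gamma_raw` or `cost_model` hold the generating
#'   coefficients).
#' @export
generate_sites <- function(config = generator_config(), seed = 1,
                           kinetics = kinetics_params(),
                           params = optimality_params()) {
  drawn <- .draw_covariates(config, seed)
  X <- drawn$X
  n <- config$n_sites
  rs <- .local_rng(seed + 1L)
  mom <- lapply(config$marginals, .marginal_moments)
  truth_attr <- list()
  if (config$mode == "regression_truth") {
    gvars <- names(config$gamma)
    mu <- vapply(mom[gvars], `[[`, 0, "mean")
    sdv <- vapply(mom[gvars], `[[`, 0, "sd")
    gamma_raw <- config$gamma / sdv
    g0_raw <- config$gamma0 - sum(gamma_raw * mu)
    v25 <- g0_raw + as.matrix(X[gvars]) %*% gamma_raw +
      rs$rnorm(n, sd = config$site_noise_sd)
    v25 <- pmax(drop(v25), 1)
    cost_i <- rep(NA_real_, n)
    truth_attr$gamma_std <- c(intercept = config$gamma0, config$gamma)
    truth_attr$gamma_raw <- c(intercept = g0_raw, gamma_raw)
    dS <- entropy_term(X$t_g, kinetics)
    vtg <- v25 * temperature_scalar(25, X$t_g, dS, kinetics)
  } else {
    cm <- config$cost_truth
    cvars <- names(cm$betas)
    cm$center <- vapply(mom[cvars], `[[`, 0, "mean")
    cm$scale <- vapply(mom[cvars], `[[`, 0, "sd")
    names(cm$center) <- names(cm$scale) <- cvars
    for (attempt in 1:5) {
      cost_i <- site_cost(cm, X)
      infeas <- attr(cost_i, "infeasible")
      opt <- optimal_vcmax(X$t_g, X$par, X$vpd, X$ca, X$elevation,
                           cost = as.numeric(cost_i), params,
                           na_infeasible = TRUE)
      infeas <- infeas | is.na(opt$vcmax)
      if (mean(infeas) <= 0.01) break
      warning("infeasible site costs for >1% of sites; narrowing coefficients",
              call. = FALSE)
      cm$betas <- cm$betas / 2
    }
    if (any(infeas)) {
      # at most 1% of sites: fall back to the intercept cost so no site is lost
      cost_i[infeas] <- cm$beta0
      opt2 <- optimal_vcmax(X$t_g[infeas], X$par[infeas], X$vpd[infeas],
                            X$ca[infeas], X$elevation[infeas],
                            cost = cm$beta0, params, na_infeasible = TRUE)
      opt$vcmax[infeas] <- opt2$vcmax
    }
    vtg <- opt$vcmax
    noise <- exp(rs$rnorm(n, sd = config$obs_noise_sd))
    vtg <- vtg * noise
    dS <- entropy_term(X$t_g, kinetics)
    v25 <- vtg * temperature_scalar(X$t_g, 25, dS, kinetics)
    truth_attr$cost_model <- cm
  }
  # replicate measurements with leaf-temperature jitter
  m <- config$measurements_per_site
  idx <- rep(seq_len(n), each = m)
  t_meas <- X$t_g[idx] + config$t_meas_offset +
    rs$rnorm(n * m, sd = config$t_meas_jitter_sd)
  t_meas <- pmin(pmax(t_meas, -15), 50)
  dSm <- entropy_term(X$t_g[idx], kinetics)
  v_tmeas <- v25[idx] * temperature_scalar(25, t_meas, dSm, kinetics) *
    exp(rs$rnorm(n * m, sd = config$meas_noise_sd))
  tab <- data.frame(site_id = sprintf("S%04d", idx),
                    latitude = NA_real_, longitude = NA_real_,
                    species = NA_character_,
                    vcmax_tmeas = v_tmeas, t_meas = t_meas,
                    X[idx, , drop = FALSE])
  tab <- tab[, intersect(.all_columns(), names(tab))]
  for (col in setdiff(.all_columns(), names(tab))) tab[[col]] <- NA_real_
  tab <- tab[.all_columns()]
  truth <- data.frame(site_id = sprintf("S%04d", seq_len(n)),
                      true_vcmax25 = v25, true_vcmax_tg = vtg,
                      true_cost = as.numeric(cost_i))
  for (nm in names(truth_attr)) attr(truth, nm) <- truth_attr[[nm]]
  list(table = .new_site_table(tab, level = "measurement",
                               source = "synthetic"),
       truth = truth)
}

#' Permute the response across sites (null fixture)
#'
#' Breaks all covariate-response links while preserving the response
#' marginal, by jointly permuting the measured Vcmax and its leaf
#' temperature across sites.
#'
#' @param table a site-mean `site_table`.
#' @param seed integer seed.
#' @return The shuffled `site_table`.
#' @export
null_shuffle <- function(table, seed = 1) {
  df <- as.data.frame(table)
  rs <- .local_rng(seed)
  perm <- rs$sample(nrow(df))
  df$vcmax_tmeas <- df$vcmax_tmeas[perm]
  df$t_meas <- df$t_meas[perm]
  .new_site_table(df, level = attr(table, "level"),
                  source = attr(table, "source"))
}
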