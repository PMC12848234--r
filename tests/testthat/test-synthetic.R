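test_that("generation is deterministic and structurally sound", {
  cfg <- generator_config(n_sites = 30)
  s1 <- generate_sites(cfg, seed = 5)
  s2 <- generate_sites(cfg, seed = 5)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$table), 30 * 3)
  expect_equal(nrow(s1$truth), 30)
  # texture fractions close
  expect_true(all(abs(s1$table$silt + s1$table$clay + s1$table$sand - 100) < 1e-9))
  expect_true(all(s1$table$vcmax_tmeas > 0))
})

test_that("a 25-degree noise-free world exposes Vcmax25 directly", {
  cfg <- generator_config(
    n_sites = 12, measurements_per_site = 1, site_noise_sd = 0,
    meas_noise_sd = 0, t_meas_offset = 0, t_meas_jitter_sd = 0,
    marginals = utils::modifyList(photocap:::.default_marginals(),
                                  list(t_g = list(type = "normal",
                                                  mean = 25, sd = 0))))
  sim <- generate_sites(cfg, seed = 2)
  expect_equal(sim$table$t_meas, rep(25, 12))
  expect_equal(sim$table$vcmax_tmeas, sim$truth$true_vcmax25)
})

test_that("zero-noise regression truth is recovered by OLS to 1e-6", {
  sim <- generate_sites(generator_config(n_sites = 60, site_noise_sd = 0,
                                         meas_noise_sd = 0,
                                         measurements_per_site = 1), seed = 10)
  sm <- aggregate_site_means(sim$table)
  gr <- attr(sim$truth, "gamma_raw")
  preds <- names(gr)[-1]
  y <- observed_vcmax(sm)$vcmax25
  fit <- stats::lm(y ~ ., data = as.data.frame(sm)[preds])
  expect_equal(unname(stats::coef(fit)), unname(gr), tolerance = 1e-6)
})

test_that("generated covariates carry the configured correlation structure", {
  cfg <- generator_config(n_sites = 4000)
  sim <- generate_sites(cfg, seed = 33)
  R_target <- implied_correlation(cfg)
  # compare on the Gaussian scale: rank correlations mapped back via the
  # Gaussian-copula identity rho = 2 sin(pi/6 * r_spearman... approx by
  # Spearman itself for these moderate correlations
  vars <- c("t_g", "vpd", "precipitation", "elevation", "soil_n", "na")
  Rs <- stats::cor(as.data.frame(sim$table)[vars], method = "spearman")
  expect_lt(max(abs(Rs - R_target[vars, vars])), 0.1)
  # key signs
  expect_gt(Rs["t_g", "vpd"], 0)
  expect_lt(Rs["t_g", "elevation"], 0)
  expect_lt(Rs["vpd", "precipitation"], 0)
})

test_that("optimality-truth tables are internally consistent", {
  sim <- exact_optimality_sim(n = 40, seed = 12)
  sm <- aggregate_site_means(sim$table)
  obs <- observed_vcmax(sm)
  expect_equal(obs$vcmax_tg, sim$truth$true_vcmax_tg, tolerance = 1e-10)
  v_model <- optimal_vcmax(sm$t_g, sm$par, sm$vpd, sm$ca, sm$elevation,
                           cost = sim$truth$true_cost)$vcmax
  expect_equal(v_model, sim$truth$true_vcmax_tg, tolerance = 1e-10)
})

test_that("overly wide cost coefficients trigger narrowing with a warning", {
  cfg <- generator_config(n_sites = 50, mode = "optimality_truth",
                          cost_truth = cost_model(
                            "edaphic", beta0 = 0.053,
                            betas = c(soil_n = -0.05, soil_ph = -0.04)))
  w <- testthat::capture_warnings(sim <- generate_sites(cfg, seed = 3))
  expect_true(any(grepl("narrowing", w)))
  expect_true(all(is.finite(sim$truth$true_vcmax_tg)))
})

test_that("null shuffling preserves marginals while destroying signal", {
  sm <- sim_site_means(100, seed = 40)
  sh <- null_shuffle(sm, seed = 2)
  expect_equal(sort(sh$vcmax_tmeas), sort(sm$vcmax_tmeas))
  expect_equal(mean(sh$vcmax_tmeas), mean(sm$vcmax_tmeas))
  expect_equal(stats::sd(sh$vcmax_tmeas), stats::sd(sm$vcmax_tmeas))
  expect_false(identical(sh$vcmax_tmeas, sm$vcmax_tmeas))
})
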