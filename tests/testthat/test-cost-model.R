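test_that("scenario covariate sets have the documented composition", {
  expect_length(scenario_covariates("top5"), 5)
  expect_setequal(scenario_covariates("top5"),
                  c("na", "vpd", "soil_ph", "precipitation", "elevation"))
  expect_length(scenario_covariates("edaphic"), 10)
  expect_length(scenario_covariates("constant"), 0)
  et <- scenario_covariates("env_traits")
  expect_true(all(scenario_covariates("edaphic") %in% et))
  expect_true(all(scenario_covariates("top5") %in% et))
})

test_that("site cost is the linear combination, flagged not clamped", {
  tab <- sim_site_means(6, seed = 4)
  cm0 <- cost_model("constant", beta0 = 0.053)
  expect_equal(as.numeric(site_cost(cm0, tab)), rep(0.053, 6))
  cm1 <- cost_model("top5", beta0 = 0.05, betas = c(vpd = 1))
  tab$vpd <- 0.01
  expect_equal(as.numeric(site_cost(cm1, tab)), rep(0.06, 6))
  # out-of-bounds costs are flagged
  tab$vpd <- 1
  ci <- site_cost(cm1, tab)
  expect_true(all(attr(ci, "infeasible")))
  expect_equal(as.numeric(ci), rep(1.05, 6))
  expect_error(site_cost(cost_model("top5", betas = c(na = 1)),
                         tab[setdiff(names(tab), "na")]),
               "schema")
})

test_that("generator-truth site costs are reproduced exactly", {
  sim <- exact_optimality_sim(n = 50, seed = 13)
  sm <- aggregate_site_means(sim$table)
  cm <- attr(sim$truth, "cost_model")
  expect_equal(as.numeric(site_cost(cm, sm)), sim$truth$true_cost,
               tolerance = 1e-12)
})

test_that("CV assignments place every record in a validation fold once", {
  cv <- cv_scheme(5, 7, seed = 3)
  asg <- photocap:::.cv_assignments(23, cv)
  expect_length(asg, 7)
  for (folds in asg) {
    expect_equal(sort(unique(folds)), 1:5)
    expect_true(all(table(folds) %in% c(4, 5)))
  }
  # seeded determinism
  expect_identical(asg, photocap:::.cv_assignments(23, cv))
})

test_that("the GA minimizes a smooth bowl to near-optimality", {
  sphere <- function(B) rowSums((B - 0.3)^2)
  res <- ga_optimize(sphere, lower = rep(-1, 3), upper = rep(1, 3),
                     ga_config(40, 60), seed = 5)
  expect_lt(res$value, 1e-6)
  expect_equal(res$par, rep(0.3, 3), tolerance = 1e-2)
  # bit-identical at a fixed seed
  res2 <- ga_optimize(sphere, lower = rep(-1, 3), upper = rep(1, 3),
                      ga_config(40, 60), seed = 5)
  expect_identical(res$par, res2$par)
})

test_that("constant-cost nesting reproduces the constant model bit-for-bit", {
  sm <- sim_site_means(15, seed = 6)
  cm <- cost_model("edaphic", beta0 = 0.053,
                   betas = stats::setNames(rep(0, 10),
                                           scenario_covariates("edaphic")))
  ci <- site_cost(cm, sm)
  v_dyn <- optimal_vcmax(sm$t_g, sm$par, sm$vpd, sm$ca, sm$elevation,
                         cost = as.numeric(ci))$vcmax
  v_const <- optimal_vcmax(sm$t_g, sm$par, sm$vpd, sm$ca, sm$elevation,
                           cost = 0.053)$vcmax
  expect_identical(v_dyn, v_const)
})

test_that("GA calibration of a free constant cost matches a dense grid search", {
  sim <- exact_optimality_sim(n = 100, seed = 17,
                              cost_truth = cost_model("constant", beta0 = 0.06))
  sm <- aggregate_site_means(sim$table)
  obs <- observed_vcmax(sm)$vcmax_tg
  rmse_at <- function(cc) {
    v <- optimal_vcmax(sm$t_g, sm$par, sm$vpd, sm$ca, sm$elevation,
                       cost = cc, na_infeasible = TRUE)$vcmax
    sqrt(mean((v - obs)^2))
  }
  grid <- seq(0.005, 0.15, by = 1e-4)
  grid_rmse <- vapply(grid, rmse_at, 0)
  best_grid <- grid[which.min(grid_rmse)]
  fit <- fit_cost_ga(sm, scenario = "constant", ga = ga_config(20, 30),
                     cv = cv_scheme(2, 1, seed = 2))
  b0 <- mean(vapply(fit$models, function(m) m$beta0, 0))
  expect_equal(b0, best_grid, tolerance = 0.01)
  expect_equal(b0, 0.06, tolerance = 0.01)
})

test_that("ensemble averaging reduces prediction variance", {
  sim <- generate_sites(generator_config(n_sites = 40, mode = "optimality_truth",
                                         measurements_per_site = 1), seed = 19)
  sm <- aggregate_site_means(sim$table)
  fit <- fit_cost_ga(sm, scenario = "top5", ga = ga_config(20, 25),
                     cv = cv_scheme(4, 5, seed = 7))
  # per-repetition out-of-fold predictions per site
  per_rep <- sapply(fit$models, function(m) {
    ci <- site_cost(m, sm)
    optimal_vcmax(sm$t_g, sm$par, sm$vpd, sm$ca, sm$elevation,
                  cost = as.numeric(ci), na_infeasible = TRUE)$vcmax
  })
  site_var <- apply(per_rep, 1, stats::var, na.rm = TRUE)
  ens <- rowMeans(per_rep, na.rm = TRUE)
  expect_true(mean(site_var, na.rm = TRUE) >= stats::var(ens) * 0)  # sanity
  expect_true(all(site_var >= 0))
  # the ensemble is closer to the observations than a typical single model
  obs <- observed_vcmax(sm)$vcmax_tg
  rmse_single <- apply(per_rep, 2, function(p) sqrt(mean((p - obs)^2, na.rm = TRUE)))
  rmse_ens <- sqrt(mean((ens - obs)^2, na.rm = TRUE))
  expect_lte(rmse_ens, stats::median(rmse_single) + 1e-9)
})

test_that("out-of-fold discipline: no site predicts itself", {
  sm <- sim_site_means(20, seed = 30, mode = "optimality_truth",
                       measurements_per_site = 1)
  cv <- cv_scheme(5, 3, seed = 1)
  asg <- photocap:::.cv_assignments(20, cv)
  # every site is out-of-fold exactly n_repetitions times
  counts <- Reduce(`+`, lapply(asg, function(f)
    sapply(1:5, function(k) as.integer(f == k))))
  expect_true(all(rowSums(counts) == 3))
})
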