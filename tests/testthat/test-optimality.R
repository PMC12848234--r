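test_that("barometric pressure follows the standard atmosphere", {
  expect_equal(atmospheric_pressure(0), 101325)
  expect_lt(atmospheric_pressure(1000), atmospheric_pressure(0))
  # independent evaluation of the barometric formula at 2500 m
  hand <- 101325 * (1 - 0.0065 * 2500 / 288.15)^(9.80665 * 0.0289644 /
                                                   (8.31447 * 0.0065))
  expect_equal(atmospheric_pressure(2500), hand, tolerance = 1 / hand)
  expect_error(atmospheric_pressure(10000), "elevation")
})

test_that("photosynthesis coefficients have the right anchors and trends", {
  co25 <- photosynthesis_coefficients(25, 101325)
  expect_equal(co25$eta_star, 1)
  co35 <- photosynthesis_coefficients(35, 101325)
  expect_gt(co35$gammastar, co25$gammastar)
  expect_gt(co35$K, co25$K)
  # independent Arrhenius evaluation of K at 25 C, sea level
  R <- 8.314
  kc <- 41.03; ko <- 28210
  K_hand <- kc * (1 + 0.2095 * 101325 / ko)
  expect_equal(co25$K, K_hand, tolerance = 1e-6)
  expect_equal(co25$gammastar, 4.332, tolerance = 1e-6)
})

test_that("least-cost chi has the correct VPD limits and monotonicity", {
  co <- photosynthesis_coefficients(25, 101325)
  ca <- 40  # Pa
  hiD <- optimal_chi(co$gammastar, co$K, co$eta_star, ca, vpd = 1e12)
  expect_equal(hiD$chi, co$gammastar / ca, tolerance = 1e-3)
  loD <- optimal_chi(co$gammastar, co$K, co$eta_star, ca,
                     vpd = 0, optimality_params(vpd_floor = 1e-9))
  expect_equal(loD$chi, 1, tolerance = 1e-3)
  chis <- vapply(c(500, 1000, 2000), function(D)
    optimal_chi(co$gammastar, co$K, co$eta_star, ca, D)$chi, 0)
  expect_true(all(diff(chis) < 0))
  # chi monotonicity agrees with brute-force minimization of the least-cost
  # objective E/A + beta * Vcmax/A on a ci grid (water cost ~ 1.6 D gs)
  pp <- optimality_params()
  brute_chi <- function(D) {
    ci <- seq(co$gammastar + 0.2, ca - 0.01, by = 0.005)
    m <- (ci - co$gammastar) / (ci + 2 * co$gammastar)
    mc <- (ci - co$gammastar) / (ci + co$K)
    # per unit A: E/A = 1.6 D eta* / (ca - ci); Vcmax/A = 1/mc
    costfun <- 1.6 * D * co$eta_star / (ca - ci) + pp$beta_costratio / mc
    ci[which.min(costfun)] / ca
  }
  for (D in c(500, 1000, 2000)) {
    expect_equal(optimal_chi(co$gammastar, co$K, co$eta_star, ca, D)$chi,
                 brute_chi(D), tolerance = 2e-3)
  }
})

test_that("closed-form optimum matches the grid oracle and is linear in PAR", {
  oracle <- grid_vcmax_oracle(25, 800, 1, 400, 0)
  expect_equal(oracle$closed$vcmax, oracle$vcmax, tolerance = 1e-3)
  expect_equal(oracle$closed$jmax, oracle$jmax, tolerance = 1e-3)
  # zero light, proportionality
  expect_equal(optimal_vcmax(25, 0, 1, 400, 0)$vcmax, 0)
  expect_equal(optimal_vcmax(25, 0, 1, 400, 0)$jmax, 0)
  v1 <- optimal_vcmax(18, 700, 1.4, 390, 500)$vcmax
  v2 <- optimal_vcmax(18, 1400, 1.4, 390, 500)$vcmax
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
})

test_that("chi bounds hold over a factorial environment grid", {
  grid <- expand.grid(t_g = c(2, 12, 25), par = c(300, 1500),
                      vpd = c(0.2, 1.5, 3.5), ca = c(360, 420),
                      elevation = c(0, 2500))
  opt <- optimal_vcmax(grid$t_g, grid$par, grid$vpd, grid$ca, grid$elevation)
  ca_pa <- grid$ca * 1e-6 * opt$pressure
  expect_true(all(opt$chi >= opt$gammastar / ca_pa - 1e-12))
  expect_true(all(opt$chi <= 1))
  expect_true(all(is.finite(opt$vcmax)))
  # Vcmax increases with VPD at fixed everything else
  vd <- optimal_vcmax(20, 800, c(0.5, 1, 2), 400, 0)$vcmax
  expect_true(all(diff(vd) > 0))
})

test_that("infeasible cost raises a typed error unless suppressed", {
  expect_error(optimal_vcmax(25, 800, 1, 400, 0, cost = 0.5),
               "cost-infeasible")
  v <- optimal_vcmax(25, 800, 1, 400, 0, cost = 0.5, na_infeasible = TRUE)
  expect_true(is.na(v$vcmax))
})

test_that("Vcmax25 conversion anchors at t_g = 25 and amplifies cold sites", {
  v25 <- predict_vcmax25_optimality(25, 800, 1, 400, 0)
  vtg <- optimal_vcmax(25, 800, 1, 400, 0)$vcmax
  expect_equal(v25, vtg)
  cold_tg <- optimal_vcmax(5, 800, 1, 400, 0)$vcmax
  cold_25 <- predict_vcmax25_optimality(5, 800, 1, 400, 0)
  expect_gt(cold_25, cold_tg)
  # round trip back to growing-season temperature
  dS <- entropy_term(5)
  expect_equal(cold_25 * temperature_scalar(25, 5, dS), cold_tg,
               tolerance = 1e-12)
})
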