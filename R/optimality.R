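# Eco-evolutionary optimality model of leaf photosynthetic capacity.
# Two nested optimizations: least-cost optimal ci/ca (chi), then maximal net
# carbon gain A_j - c * Jmax under the coordination of electron transport and
# carboxylation, giving closed-form optimal Jmax and Vcmax at growing-season
# temperature from five aboveground drivers (Tg, PAR, VPD, Ca, elevation).

#' Photosynthesis constants of the optimality model
#'
#' Biochemical and cost constants of the least-cost / coordination optimality
#' formulation. Defaults follow the established formulation of optimal
#' Vcmax prediction: photorespiratory compensation point at 25 C and sea
#' level 4.332 Pa (activation energy 37830 J mol-1), Michaelis constants for
#' carboxylation 41.03 Pa (79430) and oxygenation 28210 Pa (36380), O2 mole
#' fraction 0.2095, unit-cost ratio of transpiration vs carboxylation
#' beta = 146, light-response curvature theta = 0.85, and intrinsic quantum
#' yield phi0 = 0.257/4 mol mol-1. All are exposed for sensitivity work.
#'
#' @param gammastar25 Pa. @param ea_gammastar J mol-1.
#' @param kc25 Pa. @param ea_kc J mol-1.
#' @param ko25 Pa. @param ea_ko J mol-1.
#' @param o2_frac unitless O2 mole fraction of air.
#' @param beta_costratio unitless least-cost ratio.
#' @param theta unitless curvature of the light response, in (0, 1).
#' @param phi0 intrinsic quantum yield, mol CO2 per mol photons.
#' @param vpd_floor Pa; lower bound applied to VPD to avoid the chi = 1
#'   singularity at saturation.
#' @param R gas constant, J mol-1 K-1.
#' @return An object of class `optimality_params`.
#' @export
optimality_params <- function(gammastar25 = 4.332, ea_gammastar = 37830,
                              kc25 = 41.03, ea_kc = 79430,
                              ko25 = 28210, ea_ko = 36380,
                              o2_frac = 0.2095, beta_costratio = 146,
                              theta = 0.85, phi0 = 0.257 / 4,
                              vpd_floor = 1, R = 8.314) {
  stopifnot(theta > 0, theta < 1, phi0 > 0, beta_costratio > 0)
  structure(list(gammastar25 = gammastar25, ea_gammastar = ea_gammastar,
                 kc25 = kc25, ea_kc = ea_kc, ko25 = ko25, ea_ko = ea_ko,
                 o2_frac = o2_frac, beta_costratio = beta_costratio,
                 theta = theta, phi0 = phi0, vpd_floor = vpd_floor, R = R),
            class = "optimality_params")
}

#' Atmospheric pressure from elevation
#'
#' Standard-atmosphere barometric formula: 101325 Pa at sea level with a
#' 6.5 K km-1 lapse rate, strictly decreasing in elevation.
#'
#' @param elevation metres above sea level, within (-500, 9000). Vectorized.
#' @return Pressure, Pa.
#' @export
atmospheric_pressure <- function(elevation) {
  if (any(!is.finite(elevation) | elevation <= -500 | elevation >= 9000))
    stop("elevation outside (-500, 9000) m", call. = FALSE)
  101325 * (1 - 0.0065 * elevation / 288.15)^(9.80665 * 0.0289644 /
                                                (8.31447 * 0.0065))
}

.arrhenius <- function(k25, ea, tc, R) {
  k25 * exp(ea * (tc - 25) / (298.15 * R * (tc + 273.15)))
}

# Vogel-Fulcher-Tammann dynamic viscosity of water, Pa s
.water_viscosity <- function(tc) 2.4263e-5 * 10^(578.919 / (tc + 273.15 - 137.546))

#' Temperature- and pressure-dependent photosynthesis coefficients
#'
#' The photorespiratory compensation point Gamma* (Pa), the effective
#' Michaelis-Menten coefficient for carboxylation in air
#' `K = Kc * (1 + pO2 / Ko)` (Pa), and the viscosity of water relative to
#' 25 C (eta*), at growing-season temperature `t_g` and pressure `pressure`.
#' Gamma* scales with pressure (via the O2 partial pressure proxy) and both
#' Gamma* and K increase with temperature; eta*(25 C) = 1.
#'
#' @param t_g growing-season temperature, degrees C, in (-20, 50). Vectorized.
#' @param pressure atmospheric pressure, Pa.
#' @param params an [optimality_params()] object.
#' @return List with components `gammastar`, `K`, `eta_star`.
#' @export
photosynthesis_coefficients <- function(t_g, pressure = 101325,
                                        params = optimality_params()) {
  if (any(!is.finite(t_g) | t_g <= -20 | t_g >= 50))
    stop("t_g outside (-20, 50) degC", call. = FALSE)
  gs <- .arrhenius(params$gammastar25 * pressure / 101325, params$ea_gammastar,
                   t_g, params$R)
  kc <- .arrhenius(params$kc25, params$ea_kc, t_g, params$R)
  ko <- .arrhenius(params$ko25, params$ea_ko, t_g, params$R)
  po2 <- params$o2_frac * pressure
  list(gammastar = gs, K = kc * (1 + po2 / ko),
       eta_star = .water_viscosity(t_g) / .water_viscosity(25))
}

#' Least-cost optimal ci/ca ratio
#'
#' Solves the least-cost criterion for the ratio of leaf-internal to ambient
#' CO2 partial pressure:
#' `chi = Gamma*/ca + (1 - Gamma*/ca) * xi / (xi + sqrt(D))` with
#' `xi = sqrt(beta * (K + Gamma*) / (1.6 * eta*))`. All pressures in Pa.
#'
#' @param gammastar,K,eta_star coefficients from
#'   [photosynthesis_coefficients()].
#' @param ca ambient CO2 partial pressure, Pa.
#' @param vpd vapour pressure deficit, Pa (floored at `params$vpd_floor`).
#' @param params an [optimality_params()] object.
#' @return List with `xi` (Pa^0.5), `chi`, `ci` (Pa), `m` (light-limited CO2
#'   term) and `mc` (RuBisCO-limited CO2 term).
#' @export
optimal_chi <- function(gammastar, K, eta_star, ca, vpd,
                        params = optimality_params()) {
  if (any(ca <= 0)) stop("ca must be positive", call. = FALSE)
  D <- pmax(vpd, params$vpd_floor)
  xi <- sqrt(params$beta_costratio * (K + gammastar) / (1.6 * eta_star))
  g <- gammastar / ca
  chi <- g + (1 - g) * xi / (xi + sqrt(D))
  ci <- chi * ca
  if (any(ci <= gammastar))
    stop("degenerate environment: ci <= Gamma*, assimilation impossible",
         call. = FALSE)
  list(xi = xi, chi = chi, ci = ci,
       m = (ci - gammastar) / (ci + 2 * gammastar),
       mc = (ci - gammastar) / (ci + K))
}

# omega term of the coordination optimum. The interior maximum of the net
# gain exists only on the descending branch 0 < 4c/m < 1/(2 theta); beyond
# it the optimum is the corner Jmax = 0 (machinery unprofitable), which is
# treated as cost-infeasible so calibration can penalize it. The algebraic
# mirror solution at 4c/m > 1/(2 theta) is spurious (the same omega arises
# from the symmetric root) and is excluded for the same reason.
.omega <- function(theta, cost, m) {
  cm <- 4 * cost / m
  vterm <- 1 / (cm * (1 - theta * cm)) - 4 * theta
  om <- -(1 - 2 * theta) + sqrt(pmax((1 - theta) * vterm, 0))
  bad <- !is.finite(vterm) | vterm < 0 | cm <= 0 | cm > 1 / (2 * theta) |
    !is.finite(om) | om <= 0
  om[bad] <- NA_real_
  om
}

#' Optimal Vcmax and Jmax at growing-season temperature
#'
#' Full closed-form solution of the optimality model at one or more
#' environments: least-cost chi, then maximal net gain over Jmax of
#' light-limited assimilation minus the unit carbon cost `c * Jmax`, with
#' Vcmax set by coordination of the light- and RuBisCO-limited rates. The
#' solution is `Jmax = phi0 * I * omega` and
#' `Vcmax = phi0 * I * (m / mc) * omega* / (8 theta)`, exactly linear in PAR.
#'
#' @param t_g growing-season temperature, degrees C.
#' @param par photosynthetically active radiation I, umol m-2 s-1.
#' @param vpd vapour pressure deficit, kPa.
#' @param ca ambient CO2 mole fraction, ppm (converted to partial pressure at
#'   the site's atmospheric pressure).
#' @param elevation metres above sea level.
#' @param cost unit carbon cost of photosynthetic machinery; scalar or one
#'   value per environment. Default 0.053 (globally constant model).
#' @param params an [optimality_params()] object.
#' @param na_infeasible return NA for cost-infeasible environments instead of
#'   raising; used by the calibration penalty.
#' @return A data frame of class `optimality_internals` with one row per
#'   environment: `gammastar`, `K`, `eta_star`, `xi`, `chi`, `ci`, `m`, `mc`,
#'   `omega`, `omega_star`, `jmax`, `vcmax` (at `t_g`).
#' @examples
#' optimal_vcmax(t_g = 25, par = 800, vpd = 1, ca = 400, elevation = 0)
#' @export
optimal_vcmax <- function(t_g, par, vpd, ca, elevation, cost = 0.053,
                          params = optimality_params(),
                          na_infeasible = FALSE) {
  n <- max(length(t_g), length(par), length(vpd), length(ca),
           length(elevation), length(cost))
  t_g <- rep_len(t_g, n); par <- rep_len(par, n); vpd <- rep_len(vpd, n)
  ca <- rep_len(ca, n); elevation <- rep_len(elevation, n)
  cost <- rep_len(cost, n)
  if (any(par < 0)) stop("par must be non-negative", call. = FALSE)
  press <- atmospheric_pressure(elevation)
  co <- photosynthesis_coefficients(t_g, press, params)
  ca_pa <- ca * 1e-6 * press
  ch <- optimal_chi(co$gammastar, co$K, co$eta_star, ca_pa, vpd * 1000, params)
  theta <- params$theta
  om <- .omega(theta, cost, ch$m)
  if (any(is.na(om)) && !na_infeasible)
    stop("cost-infeasible environment: omega not real/positive (cost too large for m)",
         call. = FALSE)
  om_star <- 1 + om - sqrt((1 + om)^2 - 4 * theta * om)
  jmax <- params$phi0 * par * om
  vcmax <- params$phi0 * par * (ch$m / ch$mc) * om_star / (8 * theta)
  out <- data.frame(t_g = t_g, par = par, vpd = vpd, ca = ca,
                    elevation = elevation, cost = cost,
                    pressure = press, gammastar = co$gammastar, K = co$K,
                    eta_star = co$eta_star, xi = ch$xi, chi = ch$chi,
                    ci = ch$ci, m = ch$m, mc = ch$mc, omega = om,
                    omega_star = om_star, jmax = jmax, vcmax = vcmax)
  class(out) <- c("optimality_internals", "data.frame")
  out
}

#' Optimality-predicted Vcmax at 25 C
#'
#' Converts the optimality model's Vcmax at growing-season temperature to
#' 25 C with the peaked Arrhenius scalar (entropy term acclimated to `t_g`).
#'
#' @inheritParams optimal_vcmax
#' @param kinetics a [kinetics_params()] object.
#' @return Numeric vector of Vcmax25, umol m-2 s-1.
#' @export
predict_vcmax25_optimality <- function(t_g, par, vpd, ca, elevation,
                                       cost = 0.053,
                                       params = optimality_params(),
                                       kinetics = kinetics_params(),
                                       na_infeasible = FALSE) {
  opt <- optimal_vcmax(t_g, par, vpd, ca, elevation, cost, params,
                       na_infeasible = na_infeasible)
  dS <- entropy_term(t_g, kinetics)
  opt$vcmax * temperature_scalar(t_g, 25, dS, kinetics)
}
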