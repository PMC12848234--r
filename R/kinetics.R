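#' Enzyme-kinetics parameter set
#'
#' Parameters of the peaked (modified) Arrhenius temperature response of the
#' maximum RuBisCO carboxylation rate, with the entropy term acclimating
#' linearly to growing-season temperature following Kattge & Knorr (2007).
#'
#' @param Ha activation energy, J mol-1.
#' @param Hd deactivation energy, J mol-1. Must exceed `Ha`.
#' @param R universal gas constant, J mol-1 K-1.
#' @param deltaS_slope slope of the entropy term on growing-season
#'   temperature, J mol-1 K-1 per degree C.
#' @param deltaS_intercept intercept of the entropy term, J mol-1 K-1.
#' @return An object of class `kinetics_params` (a named list).
#' @examples
#' kp <- kinetics_params()
#' entropy_term(25, kp)
#' @export
kinetics_params <- function(Ha = 71513, Hd = 200000, R = 8.314,
                            deltaS_slope = -1.07, deltaS_intercept = 668.39) {
  stopifnot(is.numeric(Ha), is.numeric(Hd), is.numeric(R))
  if (!(Hd > Ha && Ha > 0)) stop("requires Hd > Ha > 0", call. = FALSE)
  if (R <= 0) stop("gas constant must be positive", call. = FALSE)
  structure(list(Ha = Ha, Hd = Hd, R = R,
                 deltaS_slope = deltaS_slope,
                 deltaS_intercept = deltaS_intercept),
            class = "kinetics_params")
}

#' Entropy term of the peaked Arrhenius response
#'
#' Linear acclimation of the entropy term to mean growing-season temperature:
#' `deltaS = deltaS_slope * t_g + deltaS_intercept` (defaults -1.07 and
#' 668.39 J mol-1 K-1).
#'
#' @param t_g mean growing-season temperature, degrees C. Vectorized.
#' @param params a [kinetics_params()] object.
#' @return Entropy term(s), J mol-1 K-1.
#' @export
entropy_term <- function(t_g, params = kinetics_params()) {
  if (any(!is.finite(t_g))) stop("t_g must be finite", call. = FALSE)
  params$deltaS_slope * t_g + params$deltaS_intercept
}

.check_temp_range <- function(..., lo = -50, hi = 60) {
  tt <- c(...)
  if (any(!is.finite(tt)) || any(tt <= lo) || any(tt >= hi))
    stop(sprintf("temperature outside (%g, %g) degC: %s",
                 lo, hi, paste(format(tt[!is.finite(tt) | tt <= lo | tt >= hi]),
                               collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Peaked Arrhenius temperature scalar
#'
#' The multiplicative factor `f(t0, t1)` converting Vcmax at temperature `t0`
#' to temperature `t1`: an Arrhenius activation factor times the ratio of
#' high-temperature deactivation terms, evaluated on the Kelvin scale
#' (+273.15).
#'
#' @param t0,t1 source and target leaf temperatures, degrees C, within
#'   (-50, 60).
#' @param deltaS entropy term, J mol-1 K-1 (typically from [entropy_term()]).
#' @param params a [kinetics_params()] object.
#' @return The unitless scalar `f(t0, t1)`, strictly positive.
#' @export
temperature_scalar <- function(t0, t1, deltaS, params = kinetics_params()) {
  .check_temp_range(t0, t1)
  T0 <- t0 + 273.15
  T1 <- t1 + 273.15
  Ha <- params$Ha; Hd <- params$Hd; R <- params$R
  f <- exp(Ha * (T1 - T0) / (R * T0 * T1)) *
    (1 + exp((T0 * deltaS - Hd) / (R * T0))) /
    (1 + exp((T1 * deltaS - Hd) / (R * T1)))
  if (any(!is.finite(f)))
    stop(sprintf("non-finite temperature scalar for t0=%s, t1=%s, deltaS=%s",
                 paste(format(t0), collapse = ","),
                 paste(format(t1), collapse = ","),
                 paste(format(deltaS), collapse = ",")), call. = FALSE)
  f
}

#' Convert Vcmax between leaf temperatures
#'
#' Applies the peaked Arrhenius scalar to move a Vcmax value from `t_from`
#' to `t_to`, with the entropy term acclimated to growing-season temperature
#' `t_g`. Used to derive Vcmax25 from the measurement temperature
#' (`convert_vcmax(v, t_meas, 25, t_g)`) and Vcmax at growing-season
#' temperature (`convert_vcmax(v25, 25, t_g, t_g)`).
#'
#' @param v Vcmax at `t_from`, umol CO2 m-2 s-1; must be positive.
#' @param t_from,t_to source and target temperatures, degrees C.
#' @param t_g growing-season temperature used for the entropy term, degrees C.
#' @param params a [kinetics_params()] object.
#' @return Vcmax at `t_to`, umol CO2 m-2 s-1.
#' @export
convert_vcmax <- function(v, t_from, t_to, t_g, params = kinetics_params()) {
  if (any(v <= 0, na.rm = TRUE)) stop("Vcmax must be positive", call. = FALSE)
  dS <- entropy_term(t_g, params)
  v * temperature_scalar(t_from, t_to, dS, params)
}

#' Optimum temperature of the peaked response
#'
#' Closed-form temperature at which `f(25, T)` peaks for a fixed entropy term
#' acclimated to `t_g`: `Hd / (deltaS - R * log(Ha / (Hd - Ha)))`, in Kelvin,
#' returned in degrees C. Warmer growing seasons (smaller entropy term) shift
#' the optimum upward.
#'
#' @inheritParams entropy_term
#' @return Optimum leaf temperature, degrees C.
#' @export
optimum_temperature <- function(t_g, params = kinetics_params()) {
  dS <- entropy_term(t_g, params)
  denom <- dS - params$R * log(params$Ha / (params$Hd - params$Ha))
  if (any(denom <= 0))
    stop("deltaS - R*log(Ha/(Hd-Ha)) must be positive", call. = FALSE)
  params$Hd / denom - 273.15
}
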