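#' Physical constants for canopy flux calculations
#'
#' Bundle of the physical constants used throughout the package, with the
#' standard micrometeorological defaults: von Karman's constant, the latent
#' heat of vaporization of water, the specific heat of dry air at constant
#' pressure, the molecular-weight ratio of water vapor to dry air, the
#' specific gas constant of dry air, the seconds-per-hour time conversion,
#' and the universal gas constant (used for the molar density of air).
#'
#' @param k_vonkarman dimensionless von Karman constant.
#' @param lambda_vap latent heat of vaporization, MJ kg-1.
#' @param cp specific heat of dry air at constant pressure, MJ kg-1 degC-1.
#' @param epsilon molecular weight ratio water vapor / dry air, dimensionless.
#' @param r_gas specific gas constant of dry air, J kg-1 K-1.
#' @param kt time unit conversion, s h-1.
#' @param r_universal universal gas constant, J mol-1 K-1.
#'
#' @return An object of class `physical_constants` (a named list).
#' @examples
#' physical_constants()
#' @export
physical_constants <- function(k_vonkarman = 0.41,
                               lambda_vap = 2.45,
                               cp = 0.001013,
                               epsilon = 0.622,
                               r_gas = 287,
                               kt = 3600,
                               r_universal = 8.314) {
  const <- list(
    k_vonkarman = k_vonkarman, lambda_vap = lambda_vap, cp = cp,
    epsilon = epsilon, r_gas = r_gas, kt = kt, r_universal = r_universal
  )
  bad <- vapply(const, function(x) !is.numeric(x) || length(x) != 1 ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop("physical constants must be single positive finite numbers; offending: ",
         paste(names(const)[bad], collapse = ", "), call. = FALSE)
  }
  structure(const, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

#' Saturation vapor pressure of air
#'
#' Tetens-form saturation vapor pressure
#' \eqn{e^0(T) = 0.6108 \exp(17.27 T / (T + 237.3))} in kPa, the FAO-56
#' formulation. Vectorized over temperature.
#'
#' @param t_air air temperature, degC. Must exceed -237.3.
#' @return Saturation vapor pressure, kPa.
#' @examples
#' saturation_vapor_pressure(c(0, 20, 30))
#' @export
saturation_vapor_pressure <- function(t_air) {
  .check_finite(t_air, "t_air")
  if (any(t_air <= -237.3)) {
    stop("'t_air' must be greater than -237.3 degC", call. = FALSE)
  }
  0.6108 * exp(17.27 * t_air / (t_air + 237.3))
}

#' Actual vapor pressure from relative humidity
#'
#' \eqn{e_a = e^0(T) \cdot RH / 100} in kPa.
#'
#' @param t_air air temperature, degC.
#' @param rh relative humidity, percent, in \[0, 100\].
#' @return Actual vapor pressure, kPa.
#' @examples
#' actual_vapor_pressure(30, 40)
#' @export
actual_vapor_pressure <- function(t_air, rh) {
  .check_finite(rh, "rh")
  if (any(rh < 0 | rh > 100)) {
    stop("'rh' must lie in [0, 100] percent", call. = FALSE)
  }
  saturation_vapor_pressure(t_air) * rh / 100
}

#' Mean saturation vapor pressure over a period
#'
#' \eqn{e_s = [e^0(T_{min}) + e^0(T_{max})] / 2} in kPa. With
#' `t_min == t_max` this reduces to the instantaneous saturation pressure,
#' the appropriate degenerate form for hourly records without logged
#' within-period extremes.
#'
#' @param t_min,t_max period minimum and maximum air temperature, degC.
#' @return Mean saturation vapor pressure, kPa.
#' @examples
#' mean_saturation_vapor_pressure(10, 30)
#' @export
mean_saturation_vapor_pressure <- function(t_min, t_max) {
  .check_finite(t_min, "t_min")
  .check_finite(t_max, "t_max")
  if (any(t_min > t_max)) {
    stop("'t_min' must not exceed 't_max'", call. = FALSE)
  }
  (saturation_vapor_pressure(t_min) + saturation_vapor_pressure(t_max)) / 2
}

#' Air vapor pressure deficit
#'
#' \eqn{VPD = e_s - e_a} where \eqn{e_s} is the period-mean saturation vapor
#' pressure from `t_min`/`t_max` and \eqn{e_a} the actual vapor pressure at
#' `t_air` and `rh`. For hourly records without logged extremes the defaults
#' `t_min = t_max = t_air` give the instantaneous deficit
#' \eqn{e^0(T)(1 - RH/100)}.
#'
#' A negative deficit (possible when `t_air < t_max` and humidity is high)
#' is returned as-is with a warning, never clamped: it usually flags a data
#' problem, and the big-leaf estimator downstream rejects non-positive VPD
#' explicitly.
#'
#' @param t_air air temperature, degC.
#' @param rh relative humidity, percent.
#' @param t_min,t_max period temperature extremes, degC; default `t_air`.
#' @return Vapor pressure deficit, kPa (`vapor_pressure_deficit`) or
#'   Pa (`vapor_pressure_deficit_pa`).
#' @examples
#' vapor_pressure_deficit(30, 40)       # ~2.546 kPa
#' vapor_pressure_deficit_pa(30, 40)    # ~2546 Pa
#' @export
vapor_pressure_deficit <- function(t_air, rh, t_min = t_air, t_max = t_air) {
  es <- mean_saturation_vapor_pressure(t_min, t_max)
  ea <- actual_vapor_pressure(t_air, rh)
  vpd <- es - ea
  if (any(vpd < 0)) {
    warning(sum(vpd < 0),
            " record(s) with negative VPD (supersaturation artifact); ",
            "returned unclamped", call. = FALSE)
  }
  vpd
}

#' @rdname vapor_pressure_deficit
#' @export
vapor_pressure_deficit_pa <- function(t_air, rh, t_min = t_air, t_max = t_air) {
  1000 * vapor_pressure_deficit(t_air, rh, t_min, t_max)
}

#' Slope of the saturation vapor pressure curve
#'
#' \eqn{\Delta = 4098\, e^0(T) / (T + 237.3)^2} in kPa degC-1.
#'
#' @param t_air air temperature, degC.
#' @return Slope of the saturation vapor pressure curve, kPa degC-1.
#' @examples
#' slope_vapor_pressure_curve(30)
#' @export
slope_vapor_pressure_curve <- function(t_air) {
  4098 * saturation_vapor_pressure(t_air) / (t_air + 237.3)^2
}

#' Psychrometric constant
#'
#' \eqn{\gamma = C_p P / (\epsilon \lambda)} in kPa degC-1; exactly linear in
#' atmospheric pressure.
#'
#' @param p atmospheric pressure, kPa.
#' @param constants a [physical_constants()] bundle.
#' @return Psychrometric constant, kPa degC-1.
#' @examples
#' psychrometric_constant(98.726)
#' @export
psychrometric_constant <- function(p, constants = physical_constants()) {
  .check_finite(p, "p")
  if (any(p <= 0)) stop("'p' must be positive", call. = FALSE)
  constants$cp * p / (constants$epsilon * constants$lambda_vap)
}

#' Air density
#'
#' \eqn{\rho = P / [1.01 (T + 273.3) R]} in kg m-3, with `P` converted to Pa
#' internally so the specific gas constant R = 287 J kg-1 K-1 yields kg m-3.
#'
#' @param t_air air temperature, degC.
#' @param p atmospheric pressure, kPa.
#' @param constants a [physical_constants()] bundle.
#' @return Moist air density, kg m-3.
#' @examples
#' air_density(25, 98.726)
#' @export
air_density <- function(t_air, p, constants = physical_constants()) {
  .check_finite(t_air, "t_air")
  .check_finite(p, "p")
  if (any(p <= 0)) stop("'p' must be positive", call. = FALSE)
  if (any(t_air <= -273.3)) {
    stop("'t_air' must exceed -273.3 degC", call. = FALSE)
  }
  (p * 1000) / (1.01 * (t_air + 273.3) * constants$r_gas)
}

#' Atmospheric pressure from elevation
#'
#' FAO-56 barometric relation
#' \eqn{P = 101.3 [(293 - 0.0065 z)/293]^{5.26}} in kPa.
#'
#' @param z elevation above sea level, m, in \[0, 11000).
#' @return Atmospheric pressure, kPa.
#' @examples
#' pressure_from_elevation(220)  # 98.726 kPa
#' @export
pressure_from_elevation <- function(z) {
  .check_finite(z, "z")
  if (any(z < 0 | z >= 11000)) {
    stop("'z' must lie in [0, 11000) m", call. = FALSE)
  }
  101.3 * ((293 - 0.0065 * z) / 293)^5.26
}

#' Molar density of air
#'
#' Ideal-gas molar density \eqn{n/V = P / (R_u (T + 273.15))} in mol m-3,
#' used to convert stomatal conductance from mol m-2 s-1 to m s-1. Evaluated
#' at ambient temperature and pressure by default; pass fixed values to
#' reproduce a standard-condition conversion (e.g. 41.4 mol m-3).
#'
#' @param t_air air temperature, degC.
#' @param p atmospheric pressure, kPa.
#' @param constants a [physical_constants()] bundle.
#' @return Molar density of air, mol m-3.
#' @examples
#' molar_density_air(25, 98.726)
#' @export
molar_density_air <- function(t_air, p, constants = physical_constants()) {
  .check_finite(t_air, "t_air")
  .check_finite(p, "p")
  if (any(p <= 0)) stop("'p' must be positive", call. = FALSE)
  if (any(t_air <= -273.15)) {
    stop("'t_air' must exceed -273.15 degC", call. = FALSE)
  }
  (p * 1000) / (constants$r_universal * (t_air + 273.15))
}
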