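# FAO-56 Penman-Monteith reference evapotranspiration and its auxiliary
# psychrometric quantities. All pressures in kPa, energy fluxes in
# MJ m-2 d-1, temperatures in degrees C, wind at 2 m in m s-1.

#' Saturation vapour pressure (Tetens / FAO-56)
#'
#' @param t Air temperature (degrees C); must exceed -237.3.
#' @return Saturation vapour pressure `es` in kPa:
#'   `0.6108 * exp(17.27 * t / (t + 237.3))`.
#' @export
saturation_vapor_pressure <- function(t) {
  check_number(t, "t")
  if (any(t <= -237.3)) stop("t must exceed -237.3 degrees C", call. = FALSE)
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Slope of the saturation vapour pressure curve
#'
#' @param t Air temperature (degrees C).
#' @return `Delta` in kPa per degree C: `4098 * es(t) / (t + 237.3)^2`.
#' @export
slope_svp <- function(t) {
  4098 * saturation_vapor_pressure(t) / (t + 237.3)^2
}

#' Psychrometric constant
#'
#' @param pressure Atmospheric pressure (kPa), default 101.3 (sea level).
#' @return `gamma` in kPa per degree C: `0.000665 * pressure`.
#' @export
psychrometric_constant <- function(pressure = 101.3) {
  check_number(pressure, "pressure")
  0.000665 * pressure
}

#' Atmospheric pressure at elevation
#'
#' FAO-56 barometric formula, for sites away from sea level.
#'
#' @param elevation Elevation above sea level (m).
#' @return Pressure in kPa.
#' @export
pressure_at_elevation <- function(elevation) {
  check_number(elevation, "elevation")
  101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
}

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily reference-crop evapotranspiration
#' \deqn{ETo = \frac{0.408\,\Delta (R_n - G) +
#'   \gamma \frac{900}{T + 273} u_2 (e_s - e_a)}
#'   {\Delta + \gamma (1 + 0.34\, u_2)}}{
#'   ETo = (0.408 Delta (Rn - G) + gamma 900/(T+273) u2 (es - ea)) /
#'   (Delta + gamma (1 + 0.34 u2))}
#'
#' The value can be negative when net radiation is below the soil heat flux
#' and the air is saturated; it is returned as computed unless
#' `clamp_negative = TRUE`.
#'
#' @param delta Slope of the saturation vapour pressure curve (kPa/degC).
#' @param gamma Psychrometric constant (kPa/degC).
#' @param rn Net radiation at the crop surface (MJ m-2 d-1).
#' @param g Soil heat flux (MJ m-2 d-1); ~0 at daily resolution.
#' @param t Mean air temperature at 2 m (degrees C).
#' @param u2 Mean wind speed at 2 m (m s-1).
#' @param es,ea Saturation and actual vapour pressure (kPa), `es >= ea >= 0`.
#' @param clamp_negative If `TRUE`, negative values are set to 0.
#' @return Reference evapotranspiration in mm per day. Vectorized.
#' @export
eto_penman_monteith <- function(delta, gamma, rn, g, t, u2, es, ea,
                                clamp_negative = FALSE) {
  for (nm in c("delta", "gamma", "rn", "g", "t", "u2", "es", "ea")) {
    check_number(get(nm), nm)
  }
  if (any(delta <= 0) || any(gamma <= 0)) {
    stop("delta and gamma must be positive", call. = FALSE)
  }
  if (any(u2 < 0)) stop("u2 must be >= 0", call. = FALSE)
  if (any(ea < 0) || any(es < ea - 1e-12)) {
    stop("vapour pressures must satisfy es >= ea >= 0", call. = FALSE)
  }
  num <- 0.408 * delta * (rn - g) + gamma * (900 / (t + 273)) * u2 * (es - ea)
  den <- delta + gamma * (1 + 0.34 * u2)
  out <- num / den
  if (clamp_negative) out <- pmax(0, out)
  out
}

#' Daily ETo from a weather table
#'
#' Convenience wrapper deriving the auxiliary terms the FAO-56 way:
#' `tmean` from `(tmin + tmax)/2` when absent, `es` as the mean of the
#' saturation vapour pressures at `tmax` and `tmin`, `ea` from the supplied
#' actual vapour pressure, else from mean relative humidity
#' (`ea = rh/100 * es`), else defaulting to `es` (saturated); soil heat flux
#' `g` defaults to 0 and `pressure` to 101.3 kPa (or the site value).
#'
#' @param weather Weather data frame (see [read_weather_csv()] for the
#'   dialect); needs `rn` and `u2` in addition to the temperatures.
#' @param pressure Atmospheric pressure in kPa; use
#'   [pressure_at_elevation()] for an elevation correction.
#' @param clamp_negative Passed to [eto_penman_monteith()].
#' @return Data frame `date`, `eto_mm`.
#' @export
eto_from_weather <- function(weather, pressure = 101.3,
                             clamp_negative = FALSE) {
  weather <- validate_weather(weather)
  check_columns(weather, c("rn", "u2"), "weather")
  es <- (saturation_vapor_pressure(weather$tmax) +
           saturation_vapor_pressure(weather$tmin)) / 2
  ea <- weather$ea
  if (is.null(ea)) ea <- rep(NA_real_, nrow(weather))
  need <- is.na(ea)
  if (any(need) && !is.null(weather$rh_mean)) {
    ea[need] <- weather$rh_mean[need] / 100 * es[need]
  }
  ea[is.na(ea)] <- es[is.na(ea)]
  ea <- pmin(ea, es)
  g <- weather$g
  if (is.null(g)) g <- 0
  g[is.na(g)] <- 0
  p <- weather$pressure
  if (is.null(p)) p <- pressure
  p[is.na(p)] <- pressure
  data.frame(
    date = weather$date,
    eto_mm = eto_penman_monteith(
      delta = slope_svp(weather$tmean),
      gamma = psychrometric_constant(p),
      rn = weather$rn, g = g, t = weather$tmean, u2 = weather$u2,
      es = es, ea = ea, clamp_negative = clamp_negative
    )
  )
}
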