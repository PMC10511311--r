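#' Gas-transfer velocity from channel slope and velocity
#'
#' Computes the gas-transfer (piston) velocity standardized to a Schmidt
#' number of 600 from the slope-velocity scaling
#' \eqn{k_{600} = S V \cdot \mathrm{slope} + \mathrm{intercept}},
#' defaulting to 2841 and 2.02 m/day. Strictly increasing in the product
#' S*V; at zero slope it returns the intercept.
#'
#' @param slope Channel slope, m/m (dimensionless), >= 0.
#' @param velocity Water velocity, m/s, >= 0.
#' @param constants A [ch4_constants()] list.
#' @return k600 in m/day, vectorized over inputs.
#' @export
#' @examples
#' k600_from_hydraulics(0, 0.5)        # 2.02, the intercept
#' k600_from_hydraulics(0.01, 0.5)     # 16.225
k600_from_hydraulics <- function(slope, velocity, constants = ch4_constants()) {
  if (any(slope < 0, na.rm = TRUE) || any(velocity < 0, na.rm = TRUE)) {
    stop("slope and velocity must be non-negative")
  }
  slope * velocity * constants$k600_slope + constants$k600_intercept
}

#' Water temperature from air temperature
#'
#' Linear air-to-water temperature mapping with the result floored at
#' 0 deg C. The slope and intercept live in [ch4_constants()]; the default
#' (0.67, 4.0) is a documented stream-scale regression of monthly water on
#' air temperature.
#'
#' @param t_air Air temperature, deg C.
#' @param constants A [ch4_constants()] list.
#' @return Water temperature, deg C, >= 0.
#' @export
water_temp_from_air <- function(t_air, constants = ch4_constants()) {
  stopifnot(all(is.finite(t_air)))
  pmax(0, constants$water_temp_slope * t_air + constants$water_temp_intercept)
}

#' Schmidt number of CH4 in fresh water
#'
#' Evaluates the configured Schmidt-number polynomial at the given water
#' temperature. The default coefficients are the cubic freshwater CH4
#' parameterization (Sc = 1897.8 - 114.28 t + 3.2902 t^2 - 0.039061 t^3,
#' t in deg C), which equals 600 near 17.4 deg C.
#'
#' @param t_water Water temperature, deg C, in \[0, 40\].
#' @param constants A [ch4_constants()] list.
#' @return Dimensionless Schmidt number, strictly decreasing in temperature.
#' @export
schmidt_ch4 <- function(t_water, constants = ch4_constants()) {
  if (any(t_water < 0 | t_water > 40, na.rm = TRUE)) {
    stop("t_water outside the supported range [0, 40] degC")
  }
  co <- constants$schmidt_coefs
  powers <- outer(t_water, seq_along(co) - 1, `^`)
  drop(powers %*% co)
}

#' Convert k600 to the CH4-specific gas-transfer velocity
#'
#' \eqn{k_{CH4} = k_{600} (Sc_{CH4}/600)^{-1/2}}.
#'
#' @param k600 Gas-transfer velocity at Schmidt number 600, m/day.
#' @param sc_ch4 Schmidt number of CH4 at the water temperature.
#' @return k for CH4, m/day.
#' @export
k_ch4_from_k600 <- function(k600, sc_ch4) {
  stopifnot(all(k600 > 0 | k600 == 0), all(sc_ch4 > 0))
  k600 * (sc_ch4 / 600)^(-0.5)
}

#' Atmospheric pressure from elevation
#'
#' Isothermal barometric formula, \eqn{P = \exp(-z/H)} atm with scale
#' height H from [ch4_constants()].
#'
#' @param elevation_m Elevation above sea level, m (>= -500).
#' @param constants A [ch4_constants()] list.
#' @return Pressure in atm.
#' @export
pressure_from_elevation <- function(elevation_m, constants = ch4_constants()) {
  if (any(elevation_m < -500, na.rm = TRUE)) stop("elevation below -500 m")
  exp(-elevation_m / constants$scale_height_m)
}

#' Equilibrium CH4 concentration in water
#'
#' Concentration of dissolved CH4 in equilibrium with the atmosphere at the
#' given water temperature and elevation. Solubility follows the
#' natural-log formulation
#' \eqn{\ln C = \ln x + A_1 + A_2 (100/T) + A_3 \ln(T/100) + A_4 (T/100)}
#' with C in nmol/L for an atmospheric mole fraction x, at zero salinity;
#' the partial pressure is scaled by the barometric pressure at the site
#' elevation.
#'
#' @param t_water Water temperature, deg C.
#' @param elevation_m Site elevation, m.
#' @param constants A [ch4_constants()] list.
#' @param atm_ch4_ppm Atmospheric mixing ratio override, ppm by volume.
#' @return Equilibrium concentration, mmol/m^3 (= umol/L).
#' @export
#' @examples
#' equilibrium_concentration(15, 0)   # about 0.003 mmol/m3
equilibrium_concentration <- function(t_water, elevation_m = 0,
                                      constants = ch4_constants(),
                                      atm_ch4_ppm = constants$atm_ch4_ppm) {
  t_k <- t_water + 273.15
  a <- constants$solubility_coefs
  x <- atm_ch4_ppm * 1e-6 * pressure_from_elevation(elevation_m, constants)
  ln_c_nmol <- log(x) + a[["A1"]] + a[["A2"]] * (100 / t_k) +
    a[["A3"]] * log(t_k / 100) + a[["A4"]] * (t_k / 100)
  exp(ln_c_nmol) * 1e-3  # nmol/L -> mmol/m^3
}

#' Diffusive CH4 flux across the water-air interface
#'
#' Fick's law: flux = k_CH4 * (c_w - c_eq). Negative values (influx into
#' undersaturated water) are retained, not clipped.
#'
#' @param c_w Dissolved CH4 concentration, mmol/m^3, >= 0.
#' @param c_eq Equilibrium concentration, mmol/m^3.
#' @param k_ch4 CH4-specific gas-transfer velocity, m/day.
#' @return Flux in mmol m^-2 day^-1 (positive = evasion).
#' @export
diffusive_flux <- function(c_w, c_eq, k_ch4) {
  if (any(c_w < 0, na.rm = TRUE)) stop("c_w must be non-negative")
  k_ch4 * (c_w - c_eq)
}

#' Per-reach-month gas-exchange states
#'
#' Joins hydraulic states with reach attributes and monthly air
#' temperatures to produce everything Fick's law needs: k600, water
#' temperature, Schmidt number, CH4-specific k and the equilibrium
#' concentration.
#'
#' @param hydraulics Output of [hydraulic_geometry()].
#' @param reaches Reach table (needs `reach_id`, `slope`, `elevation_m`).
#' @param air_temp Data frame `reach_id`, `month`, `t_air_c`. Alternatively
#'   a `t_water_c` column is used directly, bypassing the air-water model.
#' @param constants A [ch4_constants()] list.
#' @return Tibble with one row per reach-month: `k600`, `t_water_c`,
#'   `sc_ch4`, `k_ch4`, `c_eq`, plus the hydraulic columns.
#' @export
gas_exchange_states <- function(hydraulics, reaches, air_temp,
                                constants = ch4_constants()) {
  out <- hydraulics |>
    dplyr::inner_join(
      dplyr::select(reaches, "reach_id", "slope", "elevation_m"),
      by = "reach_id"
    ) |>
    dplyr::inner_join(air_temp, by = c("reach_id", "month"))
  if ("t_water_c" %in% names(air_temp)) {
    out$t_water_c <- pmax(0, out$t_water_c)
  } else {
    out$t_water_c <- water_temp_from_air(out$t_air_c, constants)
  }
  out$k600 <- k600_from_hydraulics(out$slope, out$velocity_ms, constants)
  out$sc_ch4 <- schmidt_ch4(out$t_water_c, constants)
  out$k_ch4 <- k_ch4_from_k600(out$k600, out$sc_ch4)
  out$c_eq <- equilibrium_concentration(out$t_water_c, out$elevation_m,
                                        constants)
  out
}
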