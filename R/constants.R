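#' Physical and empirical constants for the CH4 flux pipeline
#'
#' Returns the set of constants used throughout the pipeline, each overridable.
#' The gas-transfer model is the slope-velocity scaling
#' \eqn{k_{600} = S \times V \times 2841 + 2.02} (m/day), with coefficient
#' standard deviations 107 and 0.209 used in Monte Carlo propagation. The
#' atmospheric CH4 mixing ratio defaults to 1.83 ppm by volume (2010-2020
#' global mean). The Boltzmann constant is in eV/K and the reference
#' temperature for thermal standardization is 15 degrees C.
#'
#' @param k600_slope Slope coefficient of the S*V term, m/day per (m/m * m/s).
#' @param k600_slope_sd Standard deviation of `k600_slope`.
#' @param k600_intercept Intercept of the gas-transfer model, m/day.
#' @param k600_intercept_sd Standard deviation of `k600_intercept`.
#' @param atm_ch4_ppm Atmospheric CH4 mixing ratio, ppm by volume.
#' @param boltzmann_ev Boltzmann constant, eV/K.
#' @param t_ref_c Reference temperature for Boltzmann standardization, deg C.
#' @param molar_mass_ch4 Molar mass of CH4, g/mol.
#' @param scale_height_m Atmospheric scale height for the barometric
#'   pressure formula, m.
#' @param k_cap Gas-transfer velocity cap used by the `cap_k` flux
#'   correction, m/day (threshold above which bubble-mediated transfer
#'   dominates).
#' @param water_temp_slope,water_temp_intercept Linear air-to-water
#'   temperature mapping; water temperature is floored at 0 deg C.
#' @param schmidt_coefs Polynomial coefficients (increasing powers of
#'   temperature in deg C) of the freshwater CH4 Schmidt number.
#' @param solubility_coefs Named coefficients (A1..A4) of the natural-log
#'   solubility function for atmospheric equilibrium CH4 in fresh water
#'   (nmol/L per unit mole fraction).
#'
#' @return A list of class `ch4_constants`.
#' @export
#' @examples
#' cst <- ch4_constants()
#' cst$k600_intercept
ch4_constants <- function(k600_slope = 2841,
                          k600_slope_sd = 107,
                          k600_intercept = 2.02,
                          k600_intercept_sd = 0.209,
                          atm_ch4_ppm = 1.83,
                          boltzmann_ev = 8.617e-5,
                          t_ref_c = 15,
                          molar_mass_ch4 = 16.04,
                          scale_height_m = 8500,
                          k_cap = 35,
                          water_temp_slope = 0.67,
                          water_temp_intercept = 4.0,
                          schmidt_coefs = c(1897.8, -114.28, 3.2902, -0.039061),
                          solubility_coefs = c(A1 = -415.2807, A2 = 596.8104,
                                               A3 = 379.2599, A4 = -62.0757)) {
  cst <- list(
    k600_slope = k600_slope,
    k600_slope_sd = k600_slope_sd,
    k600_intercept = k600_intercept,
    k600_intercept_sd = k600_intercept_sd,
    atm_ch4_ppm = atm_ch4_ppm,
    boltzmann_ev = boltzmann_ev,
    t_ref_c = t_ref_c,
    molar_mass_ch4 = molar_mass_ch4,
    scale_height_m = scale_height_m,
    k_cap = k_cap,
    water_temp_slope = water_temp_slope,
    water_temp_intercept = water_temp_intercept,
    schmidt_coefs = schmidt_coefs,
    solubility_coefs = solubility_coefs
  )
  stopifnot(all(vapply(cst[1:12], is.numeric, logical(1))))
  structure(cst, class = "ch4_constants")
}

#' Downstream hydraulic-geometry coefficients
#'
#' Power-law parameters relating velocity, width and depth to discharge
#' (\eqn{V = a_V Q^{b_V}}, etc.), plus Horton-style ratios used to
#' extrapolate the network below the smallest resolved stream order. The
#' defaults are documented literature values for downstream hydraulic
#' geometry; upscaling runs should pin the set they use.
#'
#' @param a_v,b_v Velocity power law (m/s at Q = 1 m^3/s; exponent).
#' @param a_w,b_w Width power law (m; exponent).
#' @param a_d,b_d Depth power law (m; exponent).
#' @param width_ratio Geometric ratio of mean stream width between
#'   successive orders going downstream to upstream; in (0, 1).
#' @param length_ratio Ratio of total channel length in order n-1 to that
#'   in order n; > 0.
#' @param min_width_m Width floor terminating the small-stream
#'   extrapolation, m. Default 0.3 m, the median width of the smallest
#'   field-surveyed channels.
#'
#' @return A list of class `hydraulic_coefficients`.
#' @export
hydraulic_coefficients <- function(a_v = 0.19, b_v = 0.29,
                                   a_w = 7.2, b_w = 0.5,
                                   a_d = 0.27, b_d = 0.39,
                                   width_ratio = 0.5,
                                   length_ratio = 1.6,
                                   min_width_m = 0.3) {
  stopifnot(
    is.finite(c(a_v, b_v, a_w, b_w, a_d, b_d)),
    width_ratio > 0, width_ratio < 1,
    length_ratio > 0,
    min_width_m > 0
  )
  structure(list(a_v = a_v, b_v = b_v, a_w = a_w, b_w = b_w,
                 a_d = a_d, b_d = b_d,
                 width_ratio = width_ratio, length_ratio = length_ratio,
                 min_width_m = min_width_m),
            class = "hydraulic_coefficients")
}

# internal: seconds in a day, calendar month lengths (non-leap year)
SECONDS_PER_DAY <- 86400
DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
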