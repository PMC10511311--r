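#' Gas evasion footprint length
#'
#' The distance upstream over which ~95% of a dissolved gas would evade in
#' the absence of other inputs: \eqn{F_L = 3 V / K}, with the reaeration
#' coefficient \eqn{K = k / D} (per day) and V converted to m/day.
#'
#' @param velocity_ms Water velocity, m/s.
#' @param k Gas-transfer velocity, m/day.
#' @param depth_m Water depth, m.
#' @return Footprint length in metres.
#' @export
#' @examples
#' footprint_length(0.5, 10, 1)  # 12960 m
footprint_length <- function(velocity_ms, k, depth_m) {
  if (any(k <= 0) || any(depth_m <= 0) || any(velocity_ms <= 0)) {
    stop("velocity, k and depth must be positive")
  }
  3 * (velocity_ms * SECONDS_PER_DAY) / (k / depth_m)
}

#' Supply-limitation correction of the gas-transfer velocity
#'
#' When the evasion footprint exceeds the reach length, the modelled flux
#' would drain more CH4 than the reach can supply; k is then reduced so
#' that the footprint equals the reach length:
#' \eqn{k = 3 V D / R_L} (V in m/day). Reaches whose footprint already
#' fits inside the reach are untouched. The correction never increases k.
#'
#' @param k Uncorrected gas-transfer velocity, m/day.
#' @param velocity_ms Water velocity, m/s.
#' @param depth_m Depth, m.
#' @param reach_length_m Reach length, m.
#' @return Corrected k, m/day (vectorized).
#' @export
correct_supply_limited <- function(k, velocity_ms, depth_m, reach_length_m) {
  k_limit <- 3 * (velocity_ms * SECONDS_PER_DAY) * depth_m / reach_length_m
  pmin(k, k_limit)
}

#' Cap the gas-transfer velocity
#'
#' Caps k at a threshold (default 35 m/day) above which bubble-mediated
#' transfer dominates and the diffusive scaling no longer applies.
#'
#' @param k Gas-transfer velocity, m/day.
#' @param cap Cap, m/day.
#' @return min(k, cap).
#' @export
correct_cap_k <- function(k, cap = 35) {
  stopifnot(all(k >= 0, na.rm = TRUE))
  pmin(k, cap)
}

#' Cap extreme flux rates at two standard deviations above the mean
#'
#' Values above mean + 2 s.d. of the uncorrected flux population are
#' replaced by that threshold. The mean and s.d. are computed once on the
#' uncorrected population; negative (influx) values enter the statistics
#' but are never themselves capped. A degenerate population (single value
#' or zero spread) passes through unchanged.
#'
#' @param fluxes Numeric vector of flux rates, mmol m^-2 day^-1.
#' @return Capped vector of the same length.
#' @export
correct_cap_flux <- function(fluxes) {
  if (length(fluxes) < 2) {
    warning("fewer than two flux values; returned unchanged")
    return(fluxes)
  }
  s <- stats::sd(fluxes)
  if (!is.finite(s) || s == 0) return(fluxes)
  thr <- mean(fluxes) + 2 * s
  pmin(fluxes, thr)
}

#' Per-reach-month diffusive fluxes and emissions
#'
#' Combines gas-exchange states with modelled (or observed) dissolved CH4
#' concentrations into Fick's-law flux rates, applies the selected
#' a-posteriori correction to the gas-transfer velocity or flux
#' population, and converts to monthly emissions using the effective river
#' area and calendar month lengths.
#'
#' Corrections operate on the CH4-specific transfer velocity actually used
#' in Fick's law:
#' * `none` - no adjustment;
#' * `cap_k` - k capped at `constants$k_cap` (default 35 m/day);
#' * `cap_flux` - flux rates above mean + 2 s.d. of the month's
#'   (or pooled) population capped at that threshold;
#' * `supply_limited` - k reduced where the evasion footprint exceeds the
#'   reach length so that \eqn{F_L = R_L} (the default reported option).
#'
#' @param gas Output of [gas_exchange_states()].
#' @param concentrations Data frame `reach_id`, `month`, `c_hat`
#'   (mmol/m^3). Must cover every reach-month present in `gas`.
#' @param correction One of `"supply_limited"`, `"cap_k"`, `"cap_flux"`,
#'   `"none"`.
#' @param constants A [ch4_constants()] list.
#' @param cap_flux_scope For `cap_flux`: population capped per `"month"`
#'   (default) or `"pooled"` across the year.
#' @return Tibble of flux estimates: `flux_rate` (mmol m^-2 day^-1),
#'   `emission_g` (g CH4 per month), `k_used` (m/day), `corrected`,
#'   `correction_option`, `footprint_m` where defined.
#' @export
reach_fluxes <- function(gas, concentrations,
                         correction = c("supply_limited", "cap_k",
                                        "cap_flux", "none"),
                         constants = ch4_constants(),
                         cap_flux_scope = c("month", "pooled")) {
  correction <- match.arg(correction)
  cap_flux_scope <- match.arg(cap_flux_scope)
  x <- dplyr::inner_join(gas, concentrations[c("reach_id", "month", "c_hat")],
                         by = c("reach_id", "month"))
  if (nrow(x) < nrow(gas)) {
    gaps <- dplyr::anti_join(gas, concentrations,
                             by = c("reach_id", "month"))
    stop("concentrations missing for reach-months: ",
         paste(utils::head(paste(gaps$reach_id, gaps$month, sep = "/"), 10),
               collapse = ", "))
  }
  k0 <- x$k_ch4
  flowing <- x$velocity_ms > 0 & x$depth_m > 0 & k0 > 0
  k_used <- k0
  if (correction == "cap_k") {
    k_used <- correct_cap_k(k0, constants$k_cap)
  } else if (correction == "supply_limited") {
    k_used[flowing] <- correct_supply_limited(
      k0[flowing], x$velocity_ms[flowing], x$depth_m[flowing],
      x$length_m[flowing])
  }
  x$k_used <- k_used
  x$flux_rate <- diffusive_flux(x$c_hat, x$c_eq, k_used)
  if (correction == "cap_flux") {
    if (cap_flux_scope == "month") {
      x <- x |>
        dplyr::group_by(.data$month) |>
        dplyr::mutate(flux_rate = correct_cap_flux(.data$flux_rate)) |>
        dplyr::ungroup()
    } else {
      x$flux_rate <- correct_cap_flux(x$flux_rate)
    }
  }
  x$footprint_m <- NA_real_
  x$footprint_m[flowing] <- footprint_length(
    x$velocity_ms[flowing], x$k_used[flowing], x$depth_m[flowing])
  x$corrected <- x$k_used < k0 |
    (correction == "cap_flux" &
       x$flux_rate < diffusive_flux(x$c_hat, x$c_eq, k_used))
  x$correction_option <- correction
  x$emission_g <- x$flux_rate * x$effective_area_m2 *
    DAYS_IN_MONTH[x$month] * constants$molar_mass_ch4 / 1000
  x
}

#' Emission totals per month, latitudinal band and globe
#'
#' @param fluxes Output of [reach_fluxes()].
#' @param reaches Reach table carrying `latitude` per `reach_id`.
#' @param bin_width Latitudinal band width, degrees.
#' @return List: `global_tg` (Tg CH4/yr), `by_month` (Tg per month),
#'   `by_band` (Tg per band-month, see [latitudinal_bins()]).
#' @export
emission_totals <- function(fluxes, reaches, bin_width = 10) {
  g_to_tg <- 1e-12
  by_month <- fluxes |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(emission_tg = sum(.data$emission_g) * g_to_tg,
                     .groups = "drop")
  with_lat <- dplyr::inner_join(
    fluxes, dplyr::select(reaches, "reach_id", "latitude"), by = "reach_id")
  bands <- latitudinal_bins(with_lat, bin_width = bin_width,
                            value_col = "emission_g")
  bands$emission_tg <- bands$emission * g_to_tg
  list(global_tg = sum(fluxes$emission_g) * g_to_tg,
       by_month = by_month,
       by_band = bands)
}

#' Emissions from the extrapolated small-stream network
#'
#' Synthetic streams below the resolved network are assigned the mean
#' CH4-specific gas-transfer velocity, dissolved concentration and
#' equilibrium concentration of the first-order reaches of their basin
#' group, and emit over their extrapolated effective area.
#'
#' @param small_streams Output of [extrapolate_small_streams()].
#' @param gas Output of [gas_exchange_states()].
#' @param concentrations Per-reach-month `c_hat` table.
#' @param reaches Reach table with `stream_order` and `basin_group`.
#' @param constants A [ch4_constants()] list.
#' @return Tibble of per-basin-step-month emissions (`emission_g`).
#' @export
small_stream_emissions <- function(small_streams, gas, concentrations,
                                   reaches, constants = ch4_constants()) {
  first_order <- gas |>
    dplyr::inner_join(
      dplyr::select(reaches, "reach_id", "stream_order", "basin_group"),
      by = "reach_id") |>
    dplyr::inner_join(concentrations[c("reach_id", "month", "c_hat")],
                      by = c("reach_id", "month")) |>
    dplyr::group_by(.data$basin_group) |>
    dplyr::filter(.data$stream_order == min(.data$stream_order)) |>
    dplyr::group_by(.data$basin_group, .data$month) |>
    dplyr::summarise(k_ch4 = mean(.data$k_ch4), c_hat = mean(.data$c_hat),
                     c_eq = mean(.data$c_eq), .groups = "drop")
  small_streams |>
    dplyr::inner_join(first_order, by = c("basin_group", "month")) |>
    dplyr::mutate(
      flux_rate = diffusive_flux(.data$c_hat, .data$c_eq, .data$k_ch4),
      emission_g = .data$flux_rate * .data$effective_area_m2 *
        DAYS_IN_MONTH[.data$month] * constants$molar_mass_ch4 / 1000
    )
}

#' Validate modelled fluxes against direct flux measurements
#'
#' Matches flux observations to reaches (via a site-to-reach snap), keeps
#' measurements with a trustworthy k600 method, restricts to cases where
#' the modelled k600 lies within a window around the measured one,
#' averages replicate measurements per reach-month, and regresses
#' log modelled on log measured flux.
#'
#' @param fluxes Output of [reach_fluxes()] (needs `k600`).
#' @param observations Observation table with `site_id`, `month`,
#'   `flux_diff`, `k600_measured`, `k_method`.
#' @param snap Site-to-reach mapping from [snap_sites()] (mapped rows).
#' @param k_ratio_window Modelled/measured k600 window, default
#'   `c(0.5, 1.5)`.
#' @param excluded_k_methods k-method labels dropped as unclear.
#' @return List: `slope`, `intercept`, `r2`, `n`, and the matched pairs.
#' @export
validate_against_measured <- function(fluxes, observations, snap,
                                      k_ratio_window = c(0.5, 1.5),
                                      excluded_k_methods = c("other",
                                                             "not determined")) {
  obs <- observations |>
    dplyr::filter(!is.na(.data$flux_diff), !is.na(.data$k600_measured),
                  !(.data$k_method %in% excluded_k_methods)) |>
    dplyr::inner_join(snap[c("site_id", "reach_id")], by = "site_id")
  matched <- obs |>
    dplyr::inner_join(
      fluxes[c("reach_id", "month", "flux_rate", "k600")],
      by = c("reach_id", "month")) |>
    dplyr::filter(.data$k600 >= k_ratio_window[1] * .data$k600_measured,
                  .data$k600 <= k_ratio_window[2] * .data$k600_measured) |>
    dplyr::group_by(.data$reach_id, .data$month) |>
    dplyr::summarise(measured = mean(.data$flux_diff),
                     modelled = mean(.data$flux_rate), .groups = "drop") |>
    dplyr::filter(.data$measured > 0, .data$modelled > 0)
  if (nrow(matched) < 3) stop("fewer than 3 matched flux pairs")
  fit <- stats::lm(log(modelled) ~ log(measured), data = matched)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared,
       n = nrow(matched),
       pairs = matched)
}
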