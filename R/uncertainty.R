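# Precompute everything that does not change across Monte Carlo draws:
# hydraulics, water temperature, Schmidt number, equilibrium concentration,
# the supply-limitation k ceiling, and the reach-month bookkeeping.
mc_base <- function(reaches, concentrations, air_temp,
                    coeffs = hydraulic_coefficients(),
                    constants = ch4_constants()) {
  hydro <- hydraulic_geometry(reaches, coeffs)
  gas <- gas_exchange_states(hydro, reaches, air_temp, constants)
  base <- dplyr::inner_join(
    gas, concentrations[c("reach_id", "month", "c_hat", "c_sd")],
    by = c("reach_id", "month"))
  base$sc_factor <- (base$sc_ch4 / 600)^(-0.5)
  base$k_limit <- ifelse(
    base$depth_m > 0 & base$length_m > 0,
    3 * base$velocity_ms * SECONDS_PER_DAY * base$depth_m / base$length_m,
    Inf)
  base$sv <- base$slope * base$velocity_ms
  base$days <- DAYS_IN_MONTH[base$month]
  base
}

# one total (Tg/yr) for given k600 coefficients, concentrations and
# per-row area multipliers
mc_total <- function(base, k_slope, k_int, c_w, area_mult, correction,
                     constants, by = NULL) {
  k600 <- pmax(0, base$sv * k_slope + k_int)
  k <- k600 * base$sc_factor
  if (correction == "supply_limited") {
    k <- pmin(k, base$k_limit)
  } else if (correction == "cap_k") {
    k <- pmin(k, constants$k_cap)
  }
  emission_g <- k * (c_w - base$c_eq) * base$effective_area_m2 * area_mult *
    base$days * constants$molar_mass_ch4 / 1000
  if (is.null(by)) {
    sum(emission_g) * 1e-12
  } else {
    as.numeric(rowsum(emission_g, by)) * 1e-12
  }
}

#' Monte Carlo propagation of flux uncertainty to emission totals
#'
#' Propagates the three main uncertainty sources into the global emission
#' total: the gas-transfer model coefficients (drawn once per iteration,
#' shared across reaches, from their published means and s.d.), the
#' modelled concentration (per reach-month, from its prediction s.d.),
#' and the river surface area (per reach, via a width multiplier with
#' s.d. equal to the discharge CV). All draws are normal, clamped at zero
#' so no negative concentration or width enters the flux computation. The
#' active flux correction is re-applied inside every draw.
#'
#' @param reaches Reach table (needs `q_cv` and `latitude`).
#' @param concentrations Per-reach-month `c_hat` and `c_sd`, mmol/m^3.
#' @param air_temp Per-reach-month air (or water) temperature table.
#' @param coeffs,constants Hydraulic and physical configuration.
#' @param correction Flux correction applied in each draw (default
#'   `"supply_limited"`).
#' @param n Number of iterations (default 1000).
#' @param seed Integer seed.
#' @param probs Reported percentile set; both the 5-95 and 10-90 pairs by
#'   default.
#' @param share_k_draws If `TRUE` (default) the k600 coefficient draws are
#'   shared across reaches within an iteration, treating them as global
#'   model parameters; otherwise they are redrawn per reach-month.
#' @return List of class `ch4_mc`: `point_tg`, `draws` (n global totals,
#'   Tg/yr), `percentiles`, `by_month` (percentiles of monthly totals),
#'   `by_band` (percentiles of 10-degree-band totals), `n`, `seed`.
#' @export
monte_carlo_totals <- function(reaches, concentrations, air_temp,
                               coeffs = hydraulic_coefficients(),
                               constants = ch4_constants(),
                               correction = "supply_limited",
                               n = 1000, seed = 1,
                               probs = c(0.05, 0.10, 0.90, 0.95),
                               share_k_draws = TRUE) {
  if (n < 2) stop("n must be at least 2")
  base <- mc_base(reaches, concentrations, air_temp, coeffs, constants)
  base <- dplyr::inner_join(
    base, dplyr::select(reaches, "reach_id", "q_cv", "latitude"),
    by = "reach_id")
  band_edges <- seq(-90, 90, by = 10)
  base$band <- findInterval(base$latitude, band_edges,
                            rightmost.closed = TRUE)
  point <- mc_total(base, constants$k600_slope, constants$k600_intercept,
                    base$c_hat, 1, correction, constants)
  nr <- nrow(base)
  reach_index <- match(base$reach_id, unique(base$reach_id))
  n_reach <- max(reach_index)
  reach_cv <- base$q_cv[!duplicated(base$reach_id)]
  draws <- numeric(n)
  month_draws <- matrix(0, n, 12)
  band_levels <- sort(unique(base$band))
  band_draws <- matrix(0, n, length(band_levels))
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      if (share_k_draws) {
        ks <- stats::rnorm(1, constants$k600_slope, constants$k600_slope_sd)
        ki <- stats::rnorm(1, constants$k600_intercept,
                           constants$k600_intercept_sd)
      } else {
        ks <- stats::rnorm(nr, constants$k600_slope, constants$k600_slope_sd)
        ki <- stats::rnorm(nr, constants$k600_intercept,
                           constants$k600_intercept_sd)
      }
      c_w <- pmax(0, stats::rnorm(nr, base$c_hat, base$c_sd))
      w_mult <- pmax(0, stats::rnorm(n_reach, 1, reach_cv))[reach_index]
      draws[i] <- mc_total(base, ks, ki, c_w, w_mult, correction, constants)
      month_draws[i, sort(unique(base$month))] <-
        mc_total(base, ks, ki, c_w, w_mult, correction, constants,
                 by = base$month)
      band_draws[i, ] <- mc_total(base, ks, ki, c_w, w_mult, correction,
                                  constants, by = base$band)
    }
  })
  pct <- stats::quantile(draws, probs, type = 7)
  structure(list(
    point_tg = point,
    draws = draws,
    percentiles = tibble::tibble(prob = probs, total_tg = unname(pct)),
    by_month = tibble::tibble(
      month = rep(1:12, each = length(probs)),
      prob = rep(probs, 12),
      total_tg = as.numeric(apply(month_draws, 2, stats::quantile,
                                  probs = probs))),
    by_band = tibble::tibble(
      lat_lo = rep(band_edges[band_levels], each = length(probs)),
      lat_hi = rep(band_edges[band_levels + 1], each = length(probs)),
      prob = rep(probs, length(band_levels)),
      total_tg = as.numeric(apply(band_draws, 2, stats::quantile,
                                  probs = probs))),
    n = n, seed = seed, correction = correction),
    class = "ch4_mc")
}

#' One-at-a-time sensitivity of the emission total
#'
#' Shifts each of the three uncertain inputs (k600 model coefficients,
#' concentration, river area) up and down by one standard deviation while
#' holding the others at their means, and reports the resulting global
#' totals relative to the baseline: six deterministic runs.
#'
#' @inheritParams monte_carlo_totals
#' @return Tibble with columns `parameter` (`k600`, `concentration`,
#'   `area`), `direction` (+1/-1), `total_tg`, `baseline_tg`, `delta_tg`.
#' @export
oat_sensitivity <- function(reaches, concentrations, air_temp,
                            coeffs = hydraulic_coefficients(),
                            constants = ch4_constants(),
                            correction = "supply_limited") {
  base <- mc_base(reaches, concentrations, air_temp, coeffs, constants)
  base <- dplyr::inner_join(base,
                            dplyr::select(reaches, "reach_id", "q_cv"),
                            by = "reach_id")
  baseline <- mc_total(base, constants$k600_slope, constants$k600_intercept,
                       base$c_hat, 1, correction, constants)
  runs <- expand.grid(parameter = c("k600", "concentration", "area"),
                      direction = c(1, -1), stringsAsFactors = FALSE)
  runs$total_tg <- mapply(function(par, dir) {
    ks <- constants$k600_slope
    ki <- constants$k600_intercept
    c_w <- base$c_hat
    am <- 1
    if (par == "k600") {
      ks <- ks + dir * constants$k600_slope_sd
      ki <- ki + dir * constants$k600_intercept_sd
    } else if (par == "concentration") {
      c_w <- pmax(0, base$c_hat + dir * base$c_sd)
    } else {
      am <- pmax(0, 1 + dir * base$q_cv)
    }
    mc_total(base, ks, ki, c_w, am, correction, constants)
  }, runs$parameter, runs$direction)
  runs$baseline_tg <- baseline
  runs$delta_tg <- runs$total_tg - baseline
  tibble::as_tibble(runs[order(runs$parameter, -runs$direction), ])
}
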