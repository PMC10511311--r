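#' Configuration and ground truth for the synthetic data generator
#'
#' Defines the river networks, predictor tables and observation tables
#' the generator emulates, together with the ground truth planted in
#' them: the log-linear concentration model, the apparent activation
#' energy of diffusive emissions, and the log-log ebullition relation.
#' Everything downstream of the generator can therefore be checked
#' against known values.
#'
#' Concentrations are log-linear in named predictors with log-space
#' noise; diffusive fluxes follow Fick's law with the network's gas
#' exchange, multiplied by a Boltzmann factor exp(E_M x) at the true
#' activation energy; ebullitive fluxes follow the configured log-log
#' relation with the diffusive flux. Discharge is lognormal across
#' headwaters and accumulates downstream; seasonality is sinusoidal with
#' a hemisphere-dependent peak; ice-free fractions track monthly air
#' temperature at the reach latitude.
#'
#' @param n_reaches Total reaches across all basins (default 50).
#' @param n_basins Number of basin groups (independent trees).
#' @param n_sites Number of observation sites.
#' @param n_obs Number of observations.
#' @param lat_span Latitude range over which basins are placed.
#' @param q_local_log_mean,q_local_log_sd Lognormal parameters of the
#'   local (lateral) discharge input per reach, m^3/s.
#' @param seasonal_amp Amplitude of the sinusoidal discharge seasonality.
#' @param q_cv_range Range of the per-reach daily-discharge CV.
#' @param length_log_mean,length_log_sd Lognormal reach length, m.
#' @param conc_coefs Named coefficients of the true log-concentration
#'   model (`intercept` plus predictor names).
#' @param conc_noise_sd Log-space s.d. of concentration noise.
#' @param true_e_m True apparent activation energy of diffusive
#'   emissions, eV. The default (0.17) is river-like: emission in running
#'   waters is only weakly temperature dependent.
#' @param flux_noise_sd Log-space s.d. of diffusive flux noise.
#' @param eb_slope,eb_intercept,eb_noise_sd True log-log
#'   ebullition-diffusion relation (natural log) and its noise; the
#'   default slope 1 with intercept 0 places pairs around the 1:1 line.
#' @param eb_frac Fraction of observations that also report ebullition.
#' @param category_mix Named probabilities of site categories.
#' @param category_multiplier Named concentration multipliers for
#'   targeted/unrepresentable categories.
#' @param site_revisit_sd Log-space s.d. of the per-site sampling
#'   weights; larger values concentrate observations on a few intensively
#'   revisited sites, as in real monitoring programmes.
#' @param site_offset_sd_m S.d. of the site offset from the reach
#'   midpoint, m.
#' @param far_site_frac Fraction of sites displaced 1-3 km so that
#'   snapping thresholds are exercised.
#' @param k600_meas_noise_sd Log-space s.d. of measured k600 around the
#'   network value.
#' @param k_method_probs Named probabilities of k-method labels.
#' @param seed Integer seed; recorded in every output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_reaches = 50, n_basins = 3, n_sites = 60,
                         n_obs = 500,
                         lat_span = c(-20, 68),
                         q_local_log_mean = log(0.4), q_local_log_sd = 1,
                         seasonal_amp = 0.4,
                         q_cv_range = c(0.1, 0.5),
                         length_log_mean = log(6000), length_log_sd = 0.5,
                         conc_coefs = c(intercept = -2.5,
                                        wetland_frac = 2.0,
                                        soil_carbon = 0.4,
                                        t_air_c = 0.015,
                                        human_footprint = 1.0,
                                        npp = 0.5,
                                        log_slope = -0.25),
                         conc_noise_sd = 0.5,
                         true_e_m = 0.17,
                         flux_noise_sd = 0.3,
                         eb_slope = 1.0, eb_intercept = 0,
                         eb_noise_sd = 0.5, eb_frac = 0.3,
                         category_mix = c(normal = 0.82, below_wwtp = 0.04,
                                          below_dam = 0.03, fracking = 0.02,
                                          ditch = 0.04, canal = 0.02,
                                          glacial_terminus = 0.01,
                                          thaw_slump = 0.02),
                         category_multiplier = c(below_wwtp = 8, ditch = 5,
                                                 canal = 4, thaw_slump = 6,
                                                 fracking = 3, below_dam = 2,
                                                 glacial_terminus = 0.3),
                         site_revisit_sd = 1.5,
                         site_offset_sd_m = 150,
                         far_site_frac = 0.05,
                         k600_meas_noise_sd = 0.2,
                         k_method_probs = c(chamber = 0.5, tracer = 0.2,
                                            hydraulic_model = 0.15,
                                            other = 0.1,
                                            `not determined` = 0.05),
                         seed = 1) {
  stopifnot(n_reaches >= 1, n_basins >= 1, n_obs >= 1,
            conc_noise_sd >= 0, flux_noise_sd >= 0, eb_noise_sd >= 0)
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic river network
#'
#' Builds `n_basins` independent tree-structured drainage networks.
#' Discharge enters as lognormal lateral input on every reach and
#' accumulates downstream, so discharge is non-decreasing towards the
#' outlet; Strahler stream order is computed from the topology; slopes
#' decline with order on average; monthly discharge follows a sinusoid
#' peaking in the local summer; ice-free fractions are derived from
#' monthly air temperature at the reach latitude.
#'
#' @param config A [synth_config()].
#' @return A reach tibble in the schema expected by
#'   [hydraulic_geometry()]: `reach_id`, `downstream_id`, `length_m`,
#'   `slope`, `elevation_m`, `stream_order`, `basin_group`, `latitude`,
#'   `longitude`, `q_cv`, `q_01..q_12`, `ice_01..ice_12`, `dry_01..dry_12`.
#' @export
generate_network <- function(config = synth_config()) {
  withr::with_seed(config$seed, generate_network_impl(config))
}

generate_network_impl <- function(config) {
  sizes <- rep(config$n_reaches %/% config$n_basins, config$n_basins)
  extra <- config$n_reaches - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  sizes <- sizes[sizes > 0]
  basins <- lapply(seq_along(sizes), function(b) {
    n <- sizes[b]
    downstream <- c(NA_integer_,
                    if (n > 1) vapply(2:n, function(i)
                      sample.int(i - 1L, 1), integer(1)))
    # children -> Strahler order, processed leaves-first (children always
    # have a larger index than their parent)
    children <- split(seq_len(n)[-1], downstream[-1])
    ord <- integer(n)
    for (i in n:1) {
      ch <- children[[as.character(i)]]
      if (is.null(ch)) {
        ord[i] <- 1L
      } else {
        mx <- max(ord[ch])
        ord[i] <- if (sum(ord[ch] == mx) >= 2) mx + 1L else mx
      }
    }
    local_q <- stats::rlnorm(n, config$q_local_log_mean,
                             config$q_local_log_sd)
    total_q <- local_q
    if (n > 1) for (i in n:2) {
      total_q[downstream[i]] <- total_q[downstream[i]] + total_q[i]
    }
    lat0 <- stats::runif(1, config$lat_span[1], config$lat_span[2])
    lon0 <- stats::runif(1, -150, 150)
    tibble::tibble(
      idx = seq_len(n),
      downstream_idx = downstream,
      basin_group = sprintf("basin_%02d", b),
      stream_order = ord,
      q_mean = total_q,
      latitude = pmax(-89, pmin(89, lat0 + stats::rnorm(n, 0, 0.8))),
      longitude = lon0 + stats::rnorm(n, 0, 0.8),
      length_m = stats::rlnorm(n, config$length_log_mean,
                               config$length_log_sd),
      slope = pmax(1e-5, stats::rlnorm(
        n, log(0.03) - 0.45 * (ord - 1), 0.6)),
      elevation_m = pmax(0, stats::rnorm(n, 600 - 120 * ord, 150)),
      q_cv = stats::runif(n, config$q_cv_range[1], config$q_cv_range[2])
    )
  })
  reaches <- dplyr::bind_rows(basins)
  reaches$reach_id <- sprintf("r%04d", seq_len(nrow(reaches)))
  # resolve downstream ids within basins
  reaches$downstream_id <- NA_character_
  for (b in unique(reaches$basin_group)) {
    sel <- which(reaches$basin_group == b)
    di <- reaches$downstream_idx[sel]
    reaches$downstream_id[sel] <- ifelse(is.na(di), NA_character_,
                                         reaches$reach_id[sel][di])
  }
  # monthly discharge: sinusoid peaking in the local summer, mean-one
  months <- 1:12
  peak <- ifelse(reaches$latitude >= 0, 7, 1)
  for (m in months) {
    mult <- 1 + config$seasonal_amp * cos(2 * pi * (m - peak) / 12)
    reaches[[sprintf("q_%02d", m)]] <- reaches$q_mean * mult
  }
  # ice-free fraction from monthly air temperature; dry fraction zero
  for (m in months) {
    t_air <- air_temp_model(reaches$latitude, reaches$elevation_m, m)
    reaches[[sprintf("ice_%02d", m)]] <- pmin(1, pmax(0, (t_air + 6) / 8))
    reaches[[sprintf("dry_%02d", m)]] <- 0
  }
  reaches$idx <- reaches$downstream_idx <- NULL
  dplyr::relocate(reaches, "reach_id", "downstream_id")
}

# deterministic climatology: cooler at high latitude and elevation, with a
# latitude-scaled seasonal cycle peaking in the local summer
air_temp_model <- function(latitude, elevation_m, month) {
  peak <- ifelse(latitude >= 0, 7, 1)
  amp <- 4 + 0.25 * abs(latitude)
  27 - 0.55 * abs(latitude) - 0.006 * elevation_m +
    amp * cos(2 * pi * (month - peak) / 12)
}

#' Generate per-reach monthly predictor tables
#'
#' Produces the climate, soil and land-cover style predictors that drive
#' the true concentration model, plus deliberately correlated (`gpp` vs
#' `npp`) and pure-noise columns so the pruning step has work to do.
#'
#' @param reaches Output of [generate_network()].
#' @param config A [synth_config()].
#' @return Tibble with one row per reach-month: `t_air_c`, `precip_mm`,
#'   `runoff_mm`, `wetland_frac`, `soil_carbon`, `npp`, `gpp`,
#'   `human_footprint`, `log_slope`, `noise1`, `noise2`.
#' @export
generate_predictors <- function(reaches, config = synth_config()) {
  withr::with_seed(config$seed + 1, {
    n <- nrow(reaches)
    static <- tibble::tibble(
      reach_id = reaches$reach_id,
      wetland_frac = stats::rbeta(n, 1.2, 4),
      soil_carbon = stats::rlnorm(n, 0, 0.5),
      npp = stats::runif(n, 0, 1),
      human_footprint = stats::rbeta(n, 1, 6),
      log_slope = log(reaches$slope)
    )
    static$gpp <- 1.05 * static$npp + stats::rnorm(n, 0, 0.01)
    out <- dplyr::bind_rows(lapply(1:12, function(m) {
      t_air <- air_temp_model(reaches$latitude, reaches$elevation_m, m)
      dplyr::mutate(static,
                    month = m,
                    t_air_c = t_air,
                    precip_mm = stats::rlnorm(n, log(80), 0.6),
                    noise1 = stats::rnorm(n),
                    noise2 = stats::rnorm(n))
    }))
    out$runoff_mm <- 0.7 * out$precip_mm + stats::rlnorm(nrow(out),
                                                         log(10), 0.4)
    out
  })
}

# expected log concentration under the planted model
true_log_concentration <- function(predictors, config) {
  co <- config$conc_coefs
  lc <- rep(co[["intercept"]], nrow(predictors))
  for (v in setdiff(names(co), "intercept")) {
    lc <- lc + co[[v]] * predictors[[v]]
  }
  lc
}

#' Generate a synthetic observation table
#'
#' Places sites on reaches (jittered around the reach midpoint, a small
#' fraction displaced beyond typical snapping thresholds), then draws
#' observations of dissolved CH4 concentration, diffusive flux,
#' ebullitive flux, measured k600 and water temperature consistent with
#' the planted ground truth: concentrations from the log-linear predictor
#' model, diffusive fluxes from Fick's law times a Boltzmann factor at
#' the true activation energy, ebullitive fluxes from the true log-log
#' relation. Targeted site categories receive their concentration
#' multipliers.
#'
#' @param reaches Output of [generate_network()].
#' @param predictors Output of [generate_predictors()].
#' @param config A [synth_config()].
#' @param coeffs,constants Hydraulic and physical configuration used for
#'   the network's gas exchange.
#' @return Tibble with one row per observation: `site_id`, `reach_id_true`
#'   (provenance, not used by the pipeline), `latitude`, `longitude`,
#'   `date`, `month`, `site_category`, `c_ch4`, `flux_diff`, `flux_eb`,
#'   `study_id`, `k600_measured`, `k_method`, `t_water`.
#' @export
generate_observations <- function(reaches, predictors,
                                  config = synth_config(),
                                  coeffs = hydraulic_coefficients(),
                                  constants = ch4_constants()) {
  hydro <- hydraulic_geometry(reaches, coeffs)
  gas <- gas_exchange_states(
    hydro, reaches, predictors[c("reach_id", "month", "t_air_c")],
    constants)
  key <- paste(predictors$reach_id, predictors$month)
  withr::with_seed(config$seed + 2, {
    n_sites <- min(config$n_sites, nrow(reaches) * 4)
    site_reach <- sample(reaches$reach_id, n_sites, replace = TRUE)
    ri <- match(site_reach, reaches$reach_id)
    offset_m <- abs(stats::rnorm(n_sites, 0, config$site_offset_sd_m))
    far <- stats::runif(n_sites) < config$far_site_frac
    offset_m[far] <- stats::runif(sum(far), 1000, 3000)
    theta <- stats::runif(n_sites, 0, 2 * pi)
    sites <- tibble::tibble(
      site_id = sprintf("s%04d", seq_len(n_sites)),
      reach_id_true = site_reach,
      site_category = sample(names(config$category_mix), n_sites,
                             replace = TRUE, prob = config$category_mix),
      latitude = reaches$latitude[ri] + offset_m * sin(theta) / 111320,
      longitude = reaches$longitude[ri] + offset_m * cos(theta) /
        (111320 * cos(pi * reaches$latitude[ri] / 180))
    )
    site_weight <- stats::rlnorm(n_sites, 0, config$site_revisit_sd)
    obs_site <- sample.int(n_sites, config$n_obs, replace = TRUE,
                           prob = site_weight)
    month <- sample.int(12, config$n_obs, replace = TRUE)
    year <- sample(2010:2019, config$n_obs, replace = TRUE)
    obs <- sites[obs_site, ]
    obs$month <- month
    obs$date <- sprintf("%04d-%02d-15", year, month)
    gi <- match(paste(obs$reach_id_true, obs$month),
                paste(gas$reach_id, gas$month))
    pi_ <- match(paste(obs$reach_id_true, obs$month), key)
    mult <- config$category_multiplier[obs$site_category]
    mult[is.na(mult)] <- 1
    lc <- true_log_concentration(predictors[pi_, ], config) + log(mult) +
      stats::rnorm(config$n_obs, 0, config$conc_noise_sd)
    obs$c_ch4 <- exp(lc)
    obs$t_water <- gas$t_water_c[gi]
    x <- standardize_temperature(obs$t_water, constants)
    fick <- diffusive_flux(obs$c_ch4, gas$c_eq[gi], gas$k_ch4[gi])
    obs$flux_diff <- fick * exp(config$true_e_m * x +
                                  stats::rnorm(config$n_obs, 0,
                                               config$flux_noise_sd))
    obs$flux_eb <- NA_real_
    has_eb <- stats::runif(config$n_obs) < config$eb_frac & obs$flux_diff > 0
    obs$flux_eb[has_eb] <- exp(
      config$eb_intercept + config$eb_slope * log(obs$flux_diff[has_eb]) +
        stats::rnorm(sum(has_eb), 0, config$eb_noise_sd))
    obs$study_id <- paste0("study_", (obs_site %% 10) + 1)
    obs$k600_measured <- gas$k600[gi] *
      exp(stats::rnorm(config$n_obs, 0, config$k600_meas_noise_sd))
    obs$k_method <- sample(names(config$k_method_probs), config$n_obs,
                           replace = TRUE, prob = config$k_method_probs)
    obs
  })
}

#' Generate idealized Boltzmann-Arrhenius flux observations
#'
#' Direct draws from the thermal model used in activation-energy
#' recovery checks: fluxes \eqn{F = F_0 \exp(E_M x) \epsilon} with
#' lognormal noise, at temperatures uniform over a range, optionally
#' split across sites.
#'
#' @param n Number of observations.
#' @param e_m True activation energy, eV.
#' @param noise_sd Log-space noise s.d.
#' @param f0 Flux at the reference temperature, mmol m^-2 day^-1.
#' @param t_range Water-temperature range, deg C.
#' @param n_sites Number of site labels to spread observations over.
#' @param seed Integer seed.
#' @param constants A [ch4_constants()] list.
#' @return Tibble `site_id`, `t_water`, `flux_diff`.
#' @export
generate_arrhenius_fluxes <- function(n, e_m, noise_sd = 0.3, f0 = 0.15,
                                      t_range = c(2, 28), n_sites = 1,
                                      seed = 1,
                                      constants = ch4_constants()) {
  withr::with_seed(seed, {
    t_water <- stats::runif(n, t_range[1], t_range[2])
    x <- standardize_temperature(t_water, constants)
    tibble::tibble(
      site_id = sprintf("site_%02d", sample.int(n_sites, n, replace = TRUE)),
      t_water = t_water,
      flux_diff = f0 * exp(e_m * x + stats::rnorm(n, 0, noise_sd)))
  })
}
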