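#' Run the full emission-estimation pipeline on synthetic data
#'
#' Executes every stage in dependency order on data from the synthetic
#' generator: network hydraulics and gas exchange, observation
#' filtering/snapping/aggregation, predictor pruning, monthly
#' concentration models, corrected diffusive upscaling, Monte Carlo
#' uncertainty, ebullition scaling and the thermal analysis. Returns all
#' intermediate products plus a run manifest recording seeds, configuration
#' hashes and stage row counts, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A [synth_config()]; its seed drives every stage.
#' @param coeffs A [hydraulic_coefficients()] list.
#' @param constants A [ch4_constants()] list.
#' @param correction Flux correction option (default `"supply_limited"`,
#'   the reported configuration).
#' @param mc_n Monte Carlo iterations (default 200 for a fast run; use
#'   1000 for reported uncertainty intervals).
#' @param out_dir Optional directory; when given, main outputs are
#'   written as CSV/JSON alongside `manifest.json`.
#' @return List with elements `reaches`, `predictors`, `observations`,
#'   `gas`, `concentrations`, `fluxes`, `totals`, `mc`, `sensitivity`,
#'   `ebullition`, `thermal`, `model_report`, `manifest`.
#' @export
run_pipeline <- function(config = synth_config(),
                         coeffs = hydraulic_coefficients(),
                         constants = ch4_constants(),
                         correction = "supply_limited",
                         mc_n = 200, out_dir = NULL) {
  reaches <- generate_network(config)
  predictors <- generate_predictors(reaches, config)
  observations <- generate_observations(reaches, predictors, config,
                                        coeffs, constants)
  air_temp <- predictors[c("reach_id", "month", "t_air_c")]
  hydro <- hydraulic_geometry(reaches, coeffs)
  gas <- gas_exchange_states(hydro, reaches, air_temp, constants)

  filt <- filter_observations(observations)
  snap <- snap_sites(filt$retained, reaches)
  agg <- aggregate_to_reach_month(filt$retained, snap)
  agg$log_c_ch4 <- log(agg$c_ch4)
  predictor_names <- setdiff(names(predictors),
                             c("reach_id", "month"))
  model_data <- dplyr::inner_join(agg, predictors,
                                  by = c("reach_id", "month"))
  pruned <- prune_predictors(model_data, predictor_names)
  fits <- fit_monthly_models(pruned$dataset, pruned$predictors,
                             "log_c_ch4", seed = config$seed)
  pred_table <- predictors
  for (a in seq_len(nrow(pruned$log))) {
    if (pruned$log$action[a] == "log_transformed") {
      v <- pruned$log$variable[a]
      pred_table[[paste0("log_", v)]] <- log(
        pred_table[[v]] +
          as.numeric(sub(".*offset=", "", pruned$log$detail[a])))
    }
  }
  conc <- predict_with_uncertainty(fits, pred_table)
  fluxes <- reach_fluxes(gas, conc, correction = correction,
                         constants = constants)
  totals <- emission_totals(fluxes, reaches)
  mc <- monte_carlo_totals(reaches, conc, air_temp, coeffs, constants,
                           correction = correction, n = mc_n,
                           seed = config$seed)
  sens <- oat_sensitivity(reaches, conc, air_temp, coeffs, constants,
                          correction = correction)
  eb_pairs <- pair_and_filter(observations)
  eb_model <- fit_ebullition_model(eb_pairs)
  eb <- upscale_ebullition(eb_model, totals$global_tg, mc$draws)
  thermal <- site_activation_energies(observations, constants = constants)

  manifest <- list(
    package = "riverch4",
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    coeffs_hash = rlang::hash(unclass(coeffs)),
    constants_hash = rlang::hash(unclass(constants)),
    correction = correction,
    mc_n = mc_n,
    stages = list(
      n_reaches = nrow(reaches),
      n_observations = nrow(observations),
      n_retained = nrow(filt$retained),
      n_model_rows = nrow(agg),
      n_flux_rows = nrow(fluxes),
      global_total_tg = totals$global_tg,
      ebullition_total_tg = eb$central_tg
    )
  )
  out <- list(reaches = reaches, predictors = predictors,
              observations = observations, gas = gas,
              concentrations = conc, fluxes = fluxes, totals = totals,
              mc = mc, sensitivity = sens,
              ebullition = c(eb, list(model = eb_model)),
              thermal = thermal, model_report = fits$report,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fluxes, file.path(out_dir, "fluxes.csv"),
                     row.names = FALSE)
    utils::write.csv(conc, file.path(out_dir, "concentrations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(global_tg = totals$global_tg,
           mc_percentiles = mc$percentiles,
           ebullition = eb[c("central_tg", "lower_tg", "upper_tg")]),
      file.path(out_dir, "totals.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
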