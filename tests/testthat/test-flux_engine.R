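test_that("footprint length follows 3V/K and its linearities", {
  expect_equal(footprint_length(0.5, 10, 1), 12960)
  expect_equal(footprint_length(0.5, 10, 2), 2 * 12960)   # deeper -> longer
  expect_equal(footprint_length(0.5, 5, 1), 2 * 12960)    # slower gas loss
  expect_error(footprint_length(0.5, 0, 1), "positive")
})

test_that("supply-limited correction pins the footprint to the reach length", {
  # no-correction branch: footprint (12960 m) already spans the reach
  expect_equal(correct_supply_limited(10, 0.5, 1, 5000), 10)
  # correction branch: footprint 2592 m << 5000 m reach;
  # hand-computed ceiling 3 * 43200 * 1 / 5000
  expect_equal(correct_supply_limited(50, 0.5, 1, 5000), 25.92)
  # algebraic identity: recomputed footprint equals the reach length
  k_corr <- correct_supply_limited(50, 0.5, 1, 5000)
  expect_equal(footprint_length(0.5, k_corr, 1), 5000)
  # idempotence
  expect_equal(correct_supply_limited(k_corr, 0.5, 1, 5000), k_corr)
})

test_that("k capping is a simple clamp", {
  expect_equal(correct_cap_k(50), 35)
  expect_equal(correct_cap_k(10), 10)
  expect_equal(correct_cap_k(25, cap = 20), 20)
  expect_equal(correct_cap_k(correct_cap_k(50)), 35)  # idempotent
})

test_that("flux capping replaces outliers with the two-sigma threshold", {
  pop <- c(rep(1, 99), 1000)
  thr <- mean(pop) + 2 * sd(pop)
  capped <- correct_cap_flux(pop)
  expect_equal(max(capped), thr)
  expect_equal(capped[1:99], pop[1:99])
  expect_true(max(capped) <= mean(pop) + 2 * sd(pop))
  expect_equal(correct_cap_flux(rep(3, 10)), rep(3, 10))  # zero-sd passthrough
  expect_warning(correct_cap_flux(5), "fewer than two")
})

test_that("reach fluxes convert to monthly emissions with the documented unit chain", {
  reaches <- toy_reaches()[1, ]
  reaches$slope <- 0
  reaches$elevation_m <- 0
  reaches[sprintf("ice_%02d", 1:12)] <- 1
  reaches[sprintf("dry_%02d", 1:12)] <- 0
  hydro <- hydraulic_geometry(reaches)
  at <- toy_air_temp(reaches)
  at$t_water_c <- 15
  gas <- gas_exchange_states(hydro, reaches, at)
  # engineer rate = 1 mmol/m2/d and area = 1e6 m2 in June (30 days)
  gas_j <- gas[gas$month == 6, ]
  conc <- tibble::tibble(reach_id = gas_j$reach_id, month = 6,
                         c_hat = gas_j$c_eq + 1 / gas_j$k_ch4)
  gas_j$effective_area_m2 <- 1e6
  fx <- reach_fluxes(gas_j, conc, correction = "none")
  expect_equal(fx$flux_rate, 1, ignore_attr = TRUE)
  expect_equal(fx$emission_g, 1e6 * 1 * 30 * 16.04 / 1000,
               ignore_attr = TRUE)  # 0.481 t
})

test_that("missing concentration months are reported as gaps", {
  reaches <- toy_reaches()
  hydro <- hydraulic_geometry(reaches)
  gas <- gas_exchange_states(hydro, reaches, toy_air_temp(reaches))
  conc <- toy_concentrations(reaches)
  conc <- conc[!(conc$reach_id == "r2" & conc$month == 5), ]
  expect_error(reach_fluxes(gas, conc), "r2/5")
})

test_that("correction options order totals and zero area means zero total", {
  reaches <- toy_reaches()
  hydro <- hydraulic_geometry(reaches)
  gas <- gas_exchange_states(hydro, reaches, toy_air_temp(reaches))
  conc <- toy_concentrations(reaches, c_hat = 1.2)
  t_none <- sum(reach_fluxes(gas, conc, "none")$emission_g)
  t_sl <- sum(reach_fluxes(gas, conc, "supply_limited")$emission_g)
  t_capk <- sum(reach_fluxes(gas, conc, "cap_k")$emission_g)
  expect_lte(t_sl, t_none)
  expect_lte(t_capk, t_none)
  gas0 <- gas
  gas0$effective_area_m2 <- 0
  expect_equal(sum(reach_fluxes(gas0, conc, "none")$emission_g), 0)
})

test_that("under supply limitation evasion never exceeds 3x advective throughput", {
  reaches <- toy_reaches()
  hydro <- hydraulic_geometry(reaches)
  gas <- gas_exchange_states(hydro, reaches, toy_air_temp(reaches))
  conc <- toy_concentrations(reaches, c_hat = 0.9)
  fx <- reach_fluxes(gas, conc, "supply_limited")
  evasion <- fx$k_used * (fx$c_hat - fx$c_eq) * fx$width_m * fx$length_m
  throughput <- 3 * fx$c_hat * fx$velocity_ms * 86400 * fx$depth_m *
    fx$width_m
  expect_true(all(evasion <= throughput * (1 + 1e-12)))
})

test_that("emission totals aggregate by month and band and stay conserved", {
  reaches <- toy_reaches()
  hydro <- hydraulic_geometry(reaches)
  gas <- gas_exchange_states(hydro, reaches, toy_air_temp(reaches))
  fx <- reach_fluxes(gas, toy_concentrations(reaches, 1.0), "none")
  tot <- emission_totals(fx, reaches)
  expect_equal(sum(tot$by_month$emission_tg), tot$global_tg)
  expect_equal(sum(tot$by_band$emission_tg), tot$global_tg)
})

test_that("small-stream emissions inherit first-order gas exchange and concentration", {
  reaches <- toy_reaches()
  co <- hydraulic_coefficients()
  hydro <- hydraulic_geometry(reaches, co)
  gas <- gas_exchange_states(hydro, reaches, toy_air_temp(reaches))
  conc <- toy_concentrations(reaches, 1.0)
  ext <- extrapolate_small_streams(reaches, hydro, co)
  em <- small_stream_emissions(ext, gas, conc, reaches)
  expect_equal(nrow(em), nrow(ext))
  # flux rate equals Fick's law at the first-order means
  fo <- gas |>
    dplyr::filter(reach_id %in% c("r3", "r4"), month == 6)
  expect_equal(unique(em$flux_rate[em$month == 6]),
               mean(fo$k_ch4) * (1.0 - mean(fo$c_eq)))
})

test_that("validation against measured fluxes recovers self-consistent models", {
  cfg <- synth_config(n_reaches = 30, n_obs = 400, seed = 3,
                      far_site_frac = 0, conc_noise_sd = 0.3,
                      flux_noise_sd = 0.2, true_e_m = 0)
  reaches <- generate_network(cfg)
  predictors <- generate_predictors(reaches, cfg)
  obs <- generate_observations(reaches, predictors, cfg)
  hydro <- hydraulic_geometry(reaches)
  gas <- gas_exchange_states(
    hydro, reaches, predictors[c("reach_id", "month", "t_air_c")])
  # modelled concentration = the observations' underlying reach truth
  conc <- obs |>
    dplyr::group_by(reach_id = reach_id_true, month) |>
    dplyr::summarise(c_hat = mean(c_ch4), .groups = "drop")
  full_conc <- toy_concentrations(reaches, 0.5) |>
    dplyr::rows_update(conc, by = c("reach_id", "month"))
  fx <- reach_fluxes(gas, full_conc, "none")
  snap <- snap_sites(obs, reaches)
  v <- validate_against_measured(fx, obs, snap)
  expect_gt(v$r2, 0.5)
  expect_gt(v$n, 10)
  expect_true(is.finite(v$slope))
  # an exact-match k window keeps only modelled == measured k600
  expect_error(
    validate_against_measured(fx, obs[obs$k600_measured >
      2 * max(fx$k600), ], snap),
    "fewer than 3")
})
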