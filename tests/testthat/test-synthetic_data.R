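test_that("generated networks are reproducible, tree-structured and mass-consistent", {
  cfg <- synth_config(n_reaches = 40, seed = 17)
  r1 <- generate_network(cfg)
  r2 <- generate_network(cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 40)
  # every non-outlet drains to a reach in the same basin
  non_outlet <- r1[!is.na(r1$downstream_id), ]
  down <- r1[match(non_outlet$downstream_id, r1$reach_id), ]
  expect_true(all(down$basin_group == non_outlet$basin_group))
  # downstream mean discharge >= sum of direct upstream discharges
  q_mean <- rowMeans(r1[sprintf("q_%02d", 1:12)])
  up_sum <- tapply(q_mean[!is.na(r1$downstream_id)],
                   r1$downstream_id[!is.na(r1$downstream_id)], sum)
  expect_true(all(q_mean[match(names(up_sum), r1$reach_id)] >=
                    unname(up_sum) - 1e-9))
  # single-reach network: one headwater, no downstream id
  r_one <- generate_network(synth_config(n_reaches = 1, n_basins = 1))
  expect_equal(nrow(r_one), 1)
  expect_true(is.na(r_one$downstream_id))
  expect_equal(r_one$stream_order, 1L)
})

test_that("generated tables satisfy the reach invariants", {
  r <- generate_network(synth_config(n_reaches = 60, seed = 2))
  expect_true(all(r$length_m > 0))
  expect_true(all(r$slope >= 0))
  expect_true(all(r$q_cv >= 0))
  for (m in sprintf("q_%02d", 1:12)) expect_true(all(r[[m]] >= 0))
  for (m in sprintf("ice_%02d", 1:12)) {
    expect_true(all(r[[m]] >= 0 & r[[m]] <= 1))
  }
  for (m in sprintf("dry_%02d", 1:12)) {
    expect_true(all(r[[m]] >= 0 & r[[m]] <= 1))
  }
  expect_true(all(r$latitude >= -90 & r$latitude <= 90))
  # slopes decline with stream order on average
  slopes <- tapply(log(r$slope), r$stream_order, mean)
  expect_lt(slopes[length(slopes)], slopes[1])
})

test_that("observation tables are reproducible and carry the planted signals", {
  cfg <- synth_config(n_reaches = 30, n_obs = 400, seed = 21)
  net <- generate_network(cfg)
  pred <- generate_predictors(net, cfg)
  o1 <- generate_observations(net, pred, cfg)
  o2 <- generate_observations(net, pred, cfg)
  expect_identical(o1, o2)
  expect_equal(nrow(o1), 400)
  expect_true(all(o1$c_ch4 > 0))
  expect_true(all(is.finite(o1$k600_measured)))
  # category multiplier: targeted sites have elevated concentrations
  cfg_m <- synth_config(n_reaches = 30, n_obs = 1500, seed = 22,
                        conc_noise_sd = 0.2,
                        category_mix = c(normal = 0.5, below_wwtp = 0.5),
                        category_multiplier = c(below_wwtp = 10))
  net_m <- generate_network(cfg_m)
  om <- generate_observations(net_m, generate_predictors(net_m, cfg_m),
                              cfg_m)
  ratio <- mean(log(om$c_ch4[om$site_category == "below_wwtp"])) -
    mean(log(om$c_ch4[om$site_category == "normal"]))
  expect_equal(ratio, log(10), tolerance = 0.35)
})

test_that("noiseless generation lets the pipeline recover the true activation energy", {
  cfg <- synth_config(n_reaches = 25, n_obs = 600, seed = 30,
                      true_e_m = 0.5, flux_noise_sd = 0,
                      conc_noise_sd = 0,
                      conc_coefs = c(intercept = -0.5),
                      category_mix = c(normal = 1),
                      site_revisit_sd = 0)
  net <- generate_network(cfg)
  # hold temperature influence out of everything except the Boltzmann factor:
  # constant concentration, k from hydraulics, but flux scaled by exp(E x)
  obs <- generate_observations(net, generate_predictors(net, cfg), cfg)
  # regress out the gas-exchange temperature dependence using the known k
  x <- standardize_temperature(obs$t_water)
  hydro <- hydraulic_geometry(net)
  gas <- gas_exchange_states(
    hydro, net, generate_predictors(net, cfg)[c("reach_id", "month",
                                                "t_air_c")])
  gi <- match(paste(obs$reach_id_true, obs$month),
              paste(gas$reach_id, gas$month))
  fick <- gas$k_ch4[gi] * (obs$c_ch4 - gas$c_eq[gi])
  resid_slope <- coef(lm(log(obs$flux_diff) - log(fick) ~ x))[2]
  expect_equal(unname(resid_slope), 0.5, tolerance = 1e-9)
})

test_that("arrhenius generator is exact at zero noise", {
  d <- generate_arrhenius_fluxes(50, e_m = 0.96, noise_sd = 0, f0 = 0.2,
                                 seed = 4)
  x <- standardize_temperature(d$t_water)
  expect_equal(d$flux_diff, 0.2 * exp(0.96 * x))
})
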