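test_that("generator output is fully deterministic under a fixed seed", {
  cfg <- small_config(seed = 19)
  d1 <- make_domain(cfg); d2 <- make_domain(cfg)
  expect_identical(d1, d2)
  t1 <- make_truth(cfg, d1); t2 <- make_truth(cfg, d2)
  expect_identical(t1$npp, t2$npp)
  o1 <- make_pseudo_obs(t1, cfg, d1); o2 <- make_pseudo_obs(t2, cfg, d2)
  expect_identical(o1, o2)
  n1 <- make_net_flux_reference(t1, cfg, d1)
  expect_identical(n1, make_net_flux_reference(t2, cfg, d2))
  # a different seed changes the stochastic parts
  cfg2 <- small_config(seed = 20)
  expect_false(identical(make_truth(cfg2, make_domain(cfg2))$npp, t1$npp))
})

test_that("domain layout covers all classes and flags peat/permafrost", {
  cfg <- synth_config(seed = 2)
  dom <- make_domain(cfg)
  expect_equal(sort(unique(dom$cells$land_cover_class)), 1:6)
  expect_true(all(table(dom$cells$land_cover_class) > 0))
  expect_equal(sum(dom$cells$peat_fraction > 0), 40)
  expect_equal(sum(!is.na(dom$cells$active_layer_depth)), 60)
  expect_error(make_domain(synth_config(seed = 1, nx = 2, ny = 2)),
               "more classes than cells")
  # zero peat/permafrost: soil adjustment is the identity on this domain
  dom0 <- make_domain(small_config(peat_cell_fraction = 0,
                                   permafrost_cell_fraction = 0))
  tr <- make_truth(small_config(peat_cell_fraction = 0,
                                permafrost_cell_fraction = 0), dom0)
  st <- stock_dataset("t", "soilC", rowSums(tr$soil_layered),
                      layered = tr$soil_layered,
                      layer_bounds = tr$layer_bounds)
  expect_equal(adjust_soil_c(st, dom0)$values, st$values)
})

test_that("truth structure follows the configured gradient, trend and IAV", {
  cfg0 <- small_config(trend_slope = 0, iav_sd = 0)
  dom <- make_domain(cfg0)
  tr <- make_truth(cfg0, dom)
  # zero trend and IAV: trajectory constant after spin-up
  expect_lt(max(abs(sweep(tr$trajectory$X, c(2, 3), tr$trajectory$X0))), 1e-6)
  # doubling the gradient amplitude doubles truth NPP everywhere
  cfg2 <- small_config(trend_slope = 0, iav_sd = 0,
                       npp_range = 2 * cfg0$npp_range)
  tr2 <- make_truth(cfg2, dom)
  expect_equal(tr2$npp, 2 * tr$npp, tolerance = 1e-12)
  # truth apparent soil turnover equals the analytic steady-state rate
  rate <- apparent_rates(tr$trajectory, tr$system, cfg0$stock_window, "soil")
  u0 <- tr$forcing$U[1, ]
  Xs <- steady_state(tr$system, u0)
  expect_equal(rate$rate,
               u0 / rowSums(Xs[, tr$system$compartment != "vegetation"]),
               tolerance = 1e-8)
  # layered soil carbon integrates back to the 2000s soil stock
  expect_equal(rowSums(tr$soil_layered) * 1000, tr$soil_c, tolerance = 1e-6)
})

test_that("model world applies per-class biases through the emulator", {
  cfg <- small_config(trend_slope = 0, iav_sd = 0)
  dom <- make_domain(cfg)
  tr <- make_truth(cfg, dom)
  w <- make_model_world(tr, cfg, dom)
  cls <- dom$cells$land_cover_class
  expect_equal(w$npp_sim, sweep(tr$npp, 2, cfg$bias_influx[cls], `*`),
               tolerance = 1e-12)
  # carbon-use efficiency round-trips GPP to NPP exactly
  gpp <- influx_dataset("sim_gpp", "GPP", cfg$years, w$gpp_sim)
  expect_equal(unname(gpp_to_npp(gpp, w$gpp_sim, w$npp_sim)$values),
               unname(w$npp_sim), tolerance = 1e-12)
  # unit bias factors reproduce the truth world
  cfg1 <- small_config(trend_slope = 0, iav_sd = 0,
                       bias_influx = c(1, 1, 1),
                       bias_veg_turnover = c(1, 1, 1),
                       bias_soil_turnover = c(1, 1, 1))
  w1 <- make_model_world(make_truth(cfg1, dom), cfg1, dom)
  tr1 <- make_truth(cfg1, dom)
  expect_equal(w1$agb, stock_summaries(tr1$trajectory, tr1$system,
                                       cfg1$stock_window)$agb,
               tolerance = 1e-10)
  # AGB inflated only in the influx-biased class
  cfgb <- small_config(trend_slope = 0, iav_sd = 0,
                       bias_influx = c(1.3, 1, 1),
                       bias_veg_turnover = c(1, 1, 1),
                       bias_soil_turnover = c(1, 1, 1))
  wb <- make_model_world(make_truth(cfgb, dom), cfgb, dom)
  ratio <- wb$agb / w1$agb
  expect_equal(unname(ratio[cls == 1]), rep(1.3, sum(cls == 1)),
               tolerance = 1e-6)
  expect_equal(unname(ratio[cls != 1]), rep(1, sum(cls != 1)),
               tolerance = 1e-6)
  expect_error(make_model_world(tr, small_config(bias_influx = c(-1, 1, 1)),
                                dom),
               "strictly positive")
})

test_that("pseudo-observations reduce to the truth at zero noise", {
  cfg <- small_config(agb_sd = c(0, 0), soil_sd = c(0, 0), mask_fraction = 0)
  cfg$influx_roster$sd <- 0
  dom <- make_domain(cfg)
  tr <- make_truth(cfg, dom)
  obs <- make_pseudo_obs(tr, cfg, dom)
  expect_equal(obs$agb[[1]]$values, tr$agb, ignore_attr = TRUE)
  expect_equal(obs$agb[[2]]$values, tr$agb, ignore_attr = TRUE)
  expect_equal(baseline_agreement(obs$agb[[1]]$values,
                                  obs$agb[[2]]$values)$ioa, 1)
  idx <- match(2000:2014, cfg$years)
  expect_equal(unname(obs$influx$npp_sat$values), unname(tr$npp[idx, ]))
  # positive noise: baseline agreement strictly below 1
  cfgn <- small_config(agb_sd = c(0.2, 0.2))
  obsn <- make_pseudo_obs(make_truth(cfgn, dom), cfgn, dom)
  expect_lt(baseline_agreement(obsn$agb[[1]]$values,
                               obsn$agb[[2]]$values)$ioa, 1)
  # masks differ between datasets
  expect_false(identical(which(is.na(obsn$agb[[1]]$values)),
                         which(is.na(obsn$agb[[2]]$values))))
})

test_that("net-flux reference tracks truth NBP within its noise", {
  cfg <- small_config(netflux_noise_sd = 0)
  dom <- make_domain(cfg)
  tr <- make_truth(cfg, dom)
  ref <- make_net_flux_reference(tr, cfg, dom)
  expect_equal(unclass(ref), nbp_series(tr$trajectory, dom),
               ignore_attr = TRUE)
  expect_equal(attr(ref, "halfwidth"), 0.8)
  # steady-state truth: reference fluctuates around zero
  cfg0 <- small_config(trend_slope = 0, iav_sd = 0, netflux_noise_sd = 0.2)
  tr0 <- make_truth(cfg0, dom)
  ref0 <- make_net_flux_reference(tr0, cfg0, dom)
  expect_lt(abs(mean(ref0)), 0.2)
  # truth NBP agrees with the reference better than a heavily biased model
  cfgb <- small_config(bias_veg_turnover = c(2, 2, 2),
                       bias_soil_turnover = c(2, 2, 2))
  better <- 0
  for (s in 1:9) {
    cfgs <- small_config(); cfgs$seed <- 100L + s
    doms <- make_domain(cfgs)
    trs <- make_truth(cfgs, doms)
    cfgbs <- cfgb; cfgbs$seed <- cfgs$seed
    ws <- make_model_world(trs, cfgbs, doms)
    refs <- make_net_flux_reference(trs, cfgs, doms)
    yrs <- as.character(1982:2011)
    i_truth <- ioa(nbp_series(trs$trajectory, doms)[yrs], refs[yrs])
    i_model <- ioa(nbp_series(ws$trajectory, doms)[yrs], refs[yrs])
    better <- better + (i_truth > i_model)
  }
  expect_gte(better, 5) # median over seeds favours the truth
})
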