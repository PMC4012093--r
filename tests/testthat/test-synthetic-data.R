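test_that("ventilator settings imply the stated cycle arithmetic", {
  ph <- cycle_durations(ventilator_settings(rr = 8, ie_ratio = 1))
  expect_equal(ph$cycle, 7.5)
  expect_equal(ph$inspiration, 3.75)
  expect_equal(ph$expiration, 3.75)
  ph2 <- cycle_durations(ventilator_settings(rr = 12, ie_ratio = 0.5))
  expect_equal(ph2$cycle, 5)
  expect_equal(ph2$inspiration, 5 / 3)
  expect_error(ventilator_settings(rr = 0), "rr")
  expect_error(ventilator_settings(v_t = -1), "v_t")
})

test_that("simulated breaths start at multiples of the cycle duration", {
  sim <- simulate_record(model = quiet_model(), seed = 1)
  expect_equal(sim$truth$onsets_s, seq(0, 52.5, by = 7.5))
  expect_equal(dim(sim$frames$frames), c(780L, 32L, 32L))
})

test_that("each breath returns the global volume to baseline", {
  # closed-form volumes at exact cycle boundaries are zero by construction;
  # check the model directly on a dense grid
  vent <- ventilator_settings()
  model <- quiet_model()
  tt <- seq(0, 60, by = 7.5)
  v <- eitflow:::model_volumes(tt, vent, model)
  expect_lt(max(abs(rowSums(v))), 1e-9 * vent$v_t)
  # and mid-cycle the lung is inflated
  vm <- eitflow:::model_volumes(3.75, vent, model)
  expect_equal(sum(vm), vent$v_t, tolerance = 1e-9)
})

test_that("simulation is deterministic in the seed", {
  a <- simulate_record(seed = 9)
  b <- simulate_record(seed = 9)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$spiro$flow, b$spiro$flow)
  c <- simulate_record(seed = 10)
  expect_false(identical(a$frames$frames, c$frames$frames))
})

test_that("config validation and warnings", {
  expect_error(lung_model_config(fractions = c(0.5, 0.4, 0.3)), "sum to 1")
  expect_error(lung_model_config(tau_insp = 0), "positive")
  expect_warning(simulate_record(model = quiet_model(), fs_eit = 120,
                                 fs_spiro = 100, duration = 7.5, seed = 1),
                 "frame rate")
  expect_error(simulate_record(model = quiet_model(), duration = 5),
               "at least one")
})

test_that("single-compartment record yields a (0, 100, 0) distribution", {
  model <- quiet_model(fractions = c(ventral = 0, middle = 1, dorsal = 0))
  sim <- simulate_record(model = model, seed = 1)
  ana <- analyze_record(sim$frames, v_t = 345, rr = 8)
  expect_equal(unname(ana$tidal$mean), c(0, 100, 0), tolerance = 1e-9)
})

test_that("continuous ground truth matches a 10 kHz numerical oracle", {
  # single compartment, V_T = 300 ml, tau_i = 0.6 s, T_i = 3.75 s:
  # continuous PIF = (300/0.6)/(1 - exp(-6.25)) = 500.96709399872384
  # (dense-grid finite differences at 10 kHz agree to <1e-4 relative)
  vent <- ventilator_settings(v_t = 300)
  model <- quiet_model(fractions = c(ventral = 0, middle = 1, dorsal = 0),
                       tau_insp = 0.6, tau_exp = 0.6)
  tr <- analytic_ground_truth(vent, model, duration = 7.5)
  sg <- tr$spiro[tr$spiro$roi == "global", ]
  expect_equal(sg$pif, 500.96709399872384, tolerance = 1e-9)
  # dense numerical derivative oracle, independent of model_flows()
  h <- 1e-4
  tt <- seq(0, 3.75 - h, by = h)
  v <- 300 * (1 - exp(-tt / 0.6)) / (1 - exp(-3.75 / 0.6))
  expect_equal(max(diff(v)) / h, sg$pif, tolerance = 1e-4)
  # discrete 13 Hz PIF is the first backward difference after onset
  eg <- tr$eit[tr$eit$roi == "global", ]
  v13 <- 300 * (1 - exp(-(1 / 13) / 0.6)) / (1 - exp(-3.75 / 0.6))
  expect_equal(eg$pif, tr$cal_factor * v13 * 13, tolerance = 1e-9)
  expect_equal(v13 * 13, 470.18329914566425, tolerance = 1e-9)
})

test_that("linear-filling limit: PIF equals LIF equals f V_T / T_i", {
  # tau_i >> T_i means constant inspiratory flow on both grids
  vent <- ventilator_settings(v_t = 300)
  model <- quiet_model(fractions = c(ventral = 0, middle = 1, dorsal = 0),
                       tau_insp = 5000, tau_exp = 5000)
  tr <- analytic_ground_truth(vent, model, duration = 15)
  want <- 300 / 3.75
  sg <- tr$spiro[tr$spiro$roi == "global", ]
  eg <- tr$eit[tr$eit$roi == "global", ]
  expect_equal(sg$pif, want, tolerance = 1e-3)
  expect_equal(sg$lif, want, tolerance = 1e-3)
  expect_equal(eg$pif / tr$cal_factor, want, tolerance = 1e-3)
  expect_equal(eg$lif_ols / tr$cal_factor, want, tolerance = 1e-3)
})

test_that("fast expiration leaves a near-zero late expiratory flow", {
  model <- quiet_model(tau_insp = 0.15, tau_exp = 0.15)
  tr <- analytic_ground_truth(ventilator_settings(), model, duration = 15)
  eg <- tr$eit[tr$eit$roi == "global", ]
  expect_lt(abs(eg$lef_ols), 1e-3 * abs(eg$pef))
})

test_that("noise-free pipeline equals the analytic ground truth to 1e-6", {
  configs <- list(
    list(model = quiet_model(), v_t = 345),
    list(model = quiet_model(fractions = c(ventral = 0, middle = 1,
                                           dorsal = 0),
                             tau_insp = 0.6, tau_exp = 0.6), v_t = 300))
  for (cfg in configs) {
    vent <- ventilator_settings(v_t = cfg$v_t)
    sim <- simulate_record(vent, cfg$model, seed = 1)
    for (est in c("ols", "endpoint")) {
      ana <- analyze_record(sim$frames, v_t = cfg$v_t, rr = 8,
                            estimator = est)
      for (roi in c("global", "middle")) {
        tr <- sim$truth$eit[sim$truth$eit$roi == roi, ]
        s <- ana$summary[ana$summary$roi == roi, ]
        want <- c(tr$pif, tr[[paste0("lif_", est)]], tr$pef,
                  tr[[paste0("lef_", est)]])
        got <- s$mean[match(c("pif", "lif", "pef", "lef"), s$metric)]
        expect_equal(got, want, tolerance = 1e-6)
      }
    }
  }
})

test_that("lavage preset shifts ventilation away from the dependent lung", {
  base <- quiet_model()
  lav <- lavage_preset(base)
  expect_equal(sum(lav$fractions), 1)
  expect_lt(lav$fractions[["dorsal"]], base$fractions[["dorsal"]])
  lav2 <- lavage_preset(lav)
  expect_equal(sum(lav2$fractions), 1)
  expect_lt(lav2$fractions[["dorsal"]], lav$fractions[["dorsal"]])
  # spec-shaped contract on an explicit baseline
  b2 <- quiet_model(fractions = c(ventral = 0.15, middle = 0.50,
                                  dorsal = 0.35))
  l2 <- lavage_preset(b2)
  expect_lt(l2$fractions[["dorsal"]], 0.35)
  expect_equal(sum(l2$fractions), 1)

  # end-to-end: analysed dorsal percentage drops after the preset
  sim_b <- simulate_record(model = base, seed = 2)
  sim_l <- simulate_record(model = lav, seed = 2)
  td_b <- analyze_record(sim_b$frames, v_t = 345, rr = 8)$tidal
  td_l <- analyze_record(sim_l$frames, v_t = 345, rr = 8)$tidal
  expect_lt(td_l$mean[["dorsal"]], td_b$mean[["dorsal"]])
})
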