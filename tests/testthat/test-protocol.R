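test_that("an inert system stays constant over a day", {
  sys <- idc_system(params = inert_params(), media = media_config())
  st <- coculture_state(sys$media, B = 1e6, Y = 2e6, T = 3e4)
  seg <- integrate_day(st, sys, 24)
  for (i in seq_len(nrow(seg$states))) {
    expect_equal(unname(seg$states[i, ]), unname(st), tolerance = 1e-10)
  }
})

test_that("saturating nutrients recover the exponential closed form", {
  # single prototrophic bacterial population, no death, no consumption
  params <- model_params(mu = c(B = 0.45, Y = 0, T = 0),
                         death = c(B = 0, Y = 0, T = 0),
                         u = list(B = c(G = 0)),
                         sigma_L = 0, sigma_W = 0, sigma_L_basal = 0,
                         k_a = 0, k_d = 0, gamma = 0, gamma_c = 0)
  sys <- idc_system(params, donor = genotype_preset("E"),
                    recipient = genotype_preset("S"), media = media_config())
  st <- coculture_state(sys$media, B = 1e4, Y = 0)
  seg <- integrate_day(st, sys, 24, rtol = 1e-10, atol = 1e-8)
  G <- sys$media$glucose_gL
  mu_eff <- 0.45 * G / (params$K$B[["G"]] + G)
  expect_equal(seg$states[, "B_f"], 1e4 * exp(mu_eff * seg$times),
               tolerance = 1e-6)
})

test_that("glucose consumption balances new cells exactly", {
  # glucose-limited growth with no death: u_G * (new cells) = glucose drawdown
  params <- model_params(mu = c(B = 0.5, Y = 0, T = 0),
                         death = c(B = 0, Y = 0, T = 0),
                         sigma_L = 0, sigma_W = 0, sigma_L_basal = 0,
                         k_a = 0, k_d = 0, gamma = 0, gamma_c = 0)
  sys <- idc_system(params, donor = genotype_preset("E"),
                    recipient = genotype_preset("S"),
                    media = media_config(glucose_gL = 0.5))
  st <- coculture_state(sys$media, B = 1e6, Y = 0)
  seg <- integrate_day(st, sys, 48, rtol = 1e-10, atol = 1e-8)
  final <- seg$states[nrow(seg$states), ]
  new_cells <- final[["B_f"]] - 1e6
  consumed <- 0.5 - final[["n_G"]]
  expect_equal(consumed, params$u$B[["G"]] * new_cells,
               tolerance = 1e-6 * consumed)
})

test_that("the batch protocol records one sample and dilution per day", {
  sys <- crossfeeder_system()
  st <- coculture_state(sys$media)
  traj <- run_batch_protocol(st, sys, batch_protocol(n_days = 6),
                             rtol = 1e-6, atol = 1e-3)
  expect_equal(nrow(traj$daily), 6)
  expect_equal(traj$daily$day, 1:6)
  expect_equal(traj$daily$dilution, c(rep(TRUE, 5), FALSE))
  # 15-minute grid: 96 points per day plus the initial point
  expect_equal(length(traj$time_h), 6 * 96 + 1)
  expect_true(all(diff(traj$time_h) > 0))
  # expected CFU convention: half the well is plated
  expect_equal(traj$daily$expected_cfu, traj$daily$T_total * 100 / 200)
  # zero-day protocol returns the initial state only
  traj0 <- run_batch_protocol(st, sys, batch_protocol(n_days = 0))
  expect_equal(nrow(traj0$states), 1)
})

test_that("the mannose switch releases all clumps and keeps them apart", {
  sys <- crossfeeder_system()
  st <- coculture_state(sys$media)
  traj <- run_batch_protocol(st, sys,
                             batch_protocol(n_days = 4, mannose_switch_day = 2),
                             rtol = 1e-6, atol = 1e-3)
  post <- traj$day > 2
  expect_true(all(traj$states[post, "B_c"] == 0))
  expect_true(all(traj$states[post, "Y_c"] == 0))
  expect_true(all(traj$states[post, "T_c"] == 0))
  expect_true(any(traj$states[!post, "B_c"] > 0))
})

test_that("population totals are conserved by clump exchange over a day", {
  sys <- crossfeeder_system(mu = c(B = 0, Y = 0, T = 0),
                            death = c(B = 0, Y = 0, T = 0),
                            gamma = 0, gamma_c = 0)
  st <- coculture_state(sys$media, B = 5e6, Y = 3e6, T = 1e4)
  seg <- integrate_day(st, sys, 24, rtol = 1e-10, atol = 1e-8)
  B_tot <- seg$states[, "B_f"] + seg$states[, "B_c"]
  Y_tot <- seg$states[, "Y_f"] + seg$states[, "Y_c"]
  T_tot <- seg$states[, "T_f"] + seg$states[, "T_c"]
  expect_equal(B_tot, rep(5e6, length(B_tot)), tolerance = 1e-8)
  expect_equal(Y_tot, rep(3e6, length(Y_tot)), tolerance = 1e-8)
  expect_equal(T_tot, rep(1e4, length(T_tot)), tolerance = 1e-8)
})

test_that("reduced model matches full-model totals when clumping and transfer are off", {
  sys <- crossfeeder_system(k_a = 0, gamma = 0, gamma_c = 0)
  full <- run_batch_protocol(coculture_state(sys$media), sys,
                             batch_protocol(n_days = 6, sampling_interval_h = 1),
                             rtol = 1e-10, atol = 1e-8)
  red <- run_reduced_protocol(sys, batch_protocol(n_days = 6),
                              sampling_interval_h = 1,
                              rtol = 1e-10, atol = 1e-8)
  tot <- trajectory_totals(full)
  B_red <- red$value[red$species == "bacteria"]
  Y_red <- red$value[red$species == "yeast"]
  expect_equal(tot$B_total, B_red, tolerance = 1e-8)
  expect_equal(tot$Y_total + tot$T_total, Y_red, tolerance = 1e-8)
})

test_that("reduced derivatives obey the Monod growth rules", {
  sys <- crossfeeder_system()
  zero <- c(B = 0, Y = 0, n_L = 100, n_W = 100, n_U = 0, n_H = 0, n_G = 20)
  expect_equal(unname(reduced_two_species_derivatives(zero, sys)[1:2]), c(0, 0))
  # tryptophan-auxotrophic yeast cannot grow without W or a partner
  sys0 <- idc_system(media = media_config(f_L = 0, f_W = 0))
  st <- c(B = 0, Y = 1e6, n_L = 0, n_W = 0, n_U = 178, n_H = 95.4, n_G = 20)
  d <- reduced_two_species_derivatives(st, sys0)
  expect_equal(unname(d["Y"]), -sys0$params$death[["Y"]] * 1e6)
  # at full media the yeast monoculture grows
  st100 <- c(B = 0, Y = 1e6, n_L = 762, n_W = 245, n_U = 178, n_H = 95.4, n_G = 20)
  expect_gt(reduced_two_species_derivatives(st100, sys0)[["Y"]], 0)
})

test_that("solver failures surface as typed errors with the day index", {
  sys <- crossfeeder_system()
  st <- coculture_state(sys$media)
  st["B_f"] <- 1e300  # blows up immediately
  expect_error(run_batch_protocol(st, sys, batch_protocol(n_days = 2)),
               class = "idcsim_solver_failure")
})
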