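test_that("noise-free traces are exactly proportional to species totals", {
  sys <- crossfeeder_system()
  traj <- run_batch_protocol(coculture_state(sys$media), sys,
                             batch_protocol(n_days = 2), rtol = 1e-6, atol = 1e-3)
  nm <- noise_model(cv = 0, seed = 5)
  tr <- simulate_plate_traces(traj, nm)
  tot <- trajectory_totals(traj)
  mch <- tr$value[tr$channel == "mCherry"]
  expect_equal(mch, nm$yields[["mCherry"]] * tot$B_total)
  cit <- tr$value[tr$channel == "ymCitrine"]
  expect_equal(cit, nm$yields[["ymCitrine"]] * (tot$Y_total + tot$T_total))
})

test_that("a fixed seed reproduces traces exactly and CV controls the error", {
  sys <- crossfeeder_system()
  traj <- run_batch_protocol(coculture_state(sys$media), sys,
                             batch_protocol(n_days = 3), rtol = 1e-6, atol = 1e-3)
  t1 <- simulate_plate_traces(traj, noise_model(cv = 0.05, seed = 7))
  t2 <- simulate_plate_traces(traj, noise_model(cv = 0.05, seed = 7))
  expect_identical(t1, t2)
  # round-trip: normalized noisy traces against the generating model, with
  # error shrinking as the noise vanishes
  sim <- trajectory_totals(traj)
  sim_df <- data.frame(t_h = rep(sim$t_h, 2),
                       species = rep(c("bacteria", "yeast"), each = nrow(sim)),
                       value = c(sim$B_total, sim$Y_total + sim$T_total))
  err <- sapply(c(0.05, 0.01, 0), function(cv) {
    tr <- simulate_plate_traces(traj, noise_model(cv = cv, seed = 11))
    tr <- normalize_after_day1(tr)
    tr$species <- ifelse(tr$channel == "mCherry", "bacteria", "yeast")
    trajectory_error(NULL, tr, function(p) sim_df)
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-18)
})

test_that("CFU plating applies sampling fraction, dilution series and caps", {
  nm <- noise_model(count_sampling = "none", seed = 1)
  out <- simulate_cfu_plating(c(0, 40, 1e6), nm)
  expect_equal(out$raw[1], 0)
  expect_true(out$flag_floor[1])
  expect_equal(out$raw[2], 20)  # half the well is plated
  expect_true(out$flag_lawn[3])
  expect_equal(out$value[3], 500)
  # Poisson sampling is centered on the expectation (total 40 -> mean 20)
  reps <- sapply(1:300, function(i) simulate_cfu_plating(40, noise_model(seed = i))$raw)
  expect_equal(mean(reps), 20, tolerance = 0.05)
  # a dilution series keeps large totals countable
  big <- simulate_cfu_plating(1e6, noise_model(count_sampling = "none"),
                              dilutions = 10^(0:4))
  expect_false(big$flag_lawn)
  expect_equal(big$estimated_cfu, 5e5)
  expect_equal(big$dilution, 1e4)
})

test_that("colony image pairs span the ICQ range monotonically in rho", {
  p1 <- generate_colony_image_pair(size = 128, rho = 1, seed = 3)
  expect_equal(compute_icq(p1), 0.5)
  pm1 <- generate_colony_image_pair(size = 128, rho = -1, seed = 3)
  expect_equal(compute_icq(pm1), -0.5)
  p0 <- generate_colony_image_pair(size = 256, rho = 0, seed = 3)
  expect_lt(abs(compute_icq(p0)), 0.1)
  for (seed in 1:5) {
    icqs <- sapply(c(-1, -0.5, 0, 0.5, 1), function(r)
      compute_icq(generate_colony_image_pair(size = 128, rho = r, seed = seed)))
    expect_true(all(diff(icqs) > 0))
  }
  # both patterns produce valid images
  ps <- generate_colony_image_pair(size = 64, pattern = "sectors", rho = 0.5,
                                   seed = 2)
  expect_true(all(ps$a >= 0 & ps$a <= 1))
  expect_gte(compute_icq(ps), -0.5)
})

test_that("the fixture suite is reproducible and its manifest complete", {
  fx1 <- make_fixture_suite(master_seed = 3, pairings = "E_cross:S_cross",
                            lw_levels = 0.15, rho_levels = c(-1, 0, 1))
  fx2 <- make_fixture_suite(master_seed = 3, pairings = "E_cross:S_cross",
                            lw_levels = 0.15, rho_levels = c(-1, 0, 1))
  expect_identical(fx1$traces, fx2$traces)
  expect_identical(fx1$cfu, fx2$cfu)
  expect_identical(fx1$images[[1]]$a, fx2$images[[1]]$a)
  # manifest lists every run and every image with its generator parameters
  expect_equal(length(fx1$manifest$runs), 2)  # mannose on/off
  expect_setequal(unique(fx1$traces$well),
                  c(outer(sapply(fx1$manifest$runs, `[[`, "well"),
                          c("", "_monoB", "_monoY"), paste0)))
  expect_equal(fx1$manifest$ground_truth$gamma_c, 3e-4)
  expect_equal(length(fx1$manifest$images), 3)
  # traces parse back through the reader losslessly
  tmp <- tempfile(fileext = ".csv")
  write_timeseries(fx1$traces, tmp)
  back <- read_timeseries(tmp)
  expect_equal(back$value, fx1$traces$value)
  expect_equal(nrow(back), nrow(fx1$traces))
})
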