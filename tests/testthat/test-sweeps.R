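test_that("transconjugant output is zero without transfer and monotone in gamma", {
  sys <- crossfeeder_system()
  grid <- c(0, 1e-6, 1e-5, 1e-4, 1e-3)
  sw <- parameter_sweep(sys, axes = list(gamma = grid),
                        protocol = batch_protocol(n_days = 3,
                                                  sampling_interval_h = 1))
  day3 <- sw[sw$day == 3, ]
  expect_equal(day3$value[day3$gamma == 0 & day3$species == "T"] >= 0, TRUE)
  zero_rows <- sw[sw$gamma == 0, ]
  # gamma = 0 leaves only the clumped pathway; disable it too for a hard zero
  sys0 <- crossfeeder_system(gamma_c = 0)
  sw0 <- parameter_sweep(sys0, axes = list(gamma = c(0, 1e-4)),
                         protocol = batch_protocol(n_days = 2,
                                                   sampling_interval_h = 1))
  expect_true(all(sw0$value[sw0$gamma == 0] == 0))
  # monotone non-decreasing in gamma at fixed day
  v <- day3$value[order(day3$gamma)]
  expect_true(all(diff(v) >= -1e-9 * max(v)))
})

test_that("two-axis sweeps cover the full grid and annotate matches", {
  sys <- crossfeeder_system()
  sw <- parameter_sweep(sys, axes = list(gamma = c(1e-6, 1e-5),
                                         gamma_c = c(1e-5, 1e-4, 1e-3)),
                        protocol = batch_protocol(n_days = 2,
                                                  sampling_interval_h = 1),
                        match_value = NULL)
  expect_equal(nrow(sw), 2 * 3 * 2)  # grid cells x days
  expect_true(all(is.finite(sw$value)))
  sw_m <- parameter_sweep(sys, axes = list(gamma_c = c(1e-5, 3e-4)),
                          protocol = batch_protocol(n_days = 2,
                                                    sampling_interval_h = 1),
                          match_value = sw$value[nrow(sw)])
  expect_true(is.logical(sw_m$matched))
})

test_that("the proximity multiplier rescues starved donors clumped to wild-type yeast", {
  sys <- idc_system(donor = genotype_preset("E_cross"),
                    recipient = genotype_preset("S"),
                    media = media_config(f_L = 0, f_W = 1))
  sw <- parameter_sweep(sys, axes = list(P = c(1, 10, 50, 100, 300)),
                        protocol = batch_protocol(sampling_interval_h = 1),
                        observable = "species_totals")
  b6 <- sw[sw$day == 6 & sw$species == "B", ]
  b6 <- b6[order(b6$P), ]
  # donor benefit grows monotonically with P and spans extinction to persistence
  expect_true(all(diff(b6$value) > 0))
  expect_gt(b6$value[nrow(b6)], 10 * b6$value[1])
})

test_that("the rescue phase map classifies collapse, suppression and rescue", {
  protocol <- batch_protocol(sampling_interval_h = 1)
  pm <- rescue_phase_map(genotype_preset("E_cross"), genotype_preset("S_his"),
                         f_L_grid = 0, f_H_grid = c(0, 0.05, 1),
                         params = model_params(P = 50), protocol = protocol)
  expect_setequal(names(pm)[1:2], c("f_L", "f_H"))
  # with transfer disabled nothing is rescued at f_H = 0
  pm0 <- rescue_phase_map(genotype_preset("E_cross"), genotype_preset("S_his"),
                          f_L_grid = 0, f_H_grid = 0,
                          params = model_params(P = 50, gamma = 0, gamma_c = 0),
                          protocol = protocol)
  expect_true(all(pm0$class != "rescued"))
  # at full histidine the recipient needs no rescue, independent of gamma
  pm1 <- rescue_phase_map(genotype_preset("E_cross"), genotype_preset("S_his"),
                          f_L_grid = 0, f_H_grid = 1,
                          params = model_params(P = 50, gamma = 0, gamma_c = 0),
                          protocol = protocol)
  expect_equal(pm1$class, "rescued")
})
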