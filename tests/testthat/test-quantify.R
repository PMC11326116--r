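make_traces <- function() {
  data.frame(
    well = "A1",
    t_h = rep(c(10, 30, 50), 2),
    channel = rep(c("mCherry", "ymCitrine"), each = 3),
    value = c(3000, 500, 2000, 10, 40, 80)
  )
}

test_that("post-day-1 normalization divides by the per-channel late maximum", {
  out <- normalize_after_day1(make_traces())
  # mCherry: post-cutoff max is 2000, so the 500 reading becomes 0.25
  expect_equal(out$value[out$channel == "mCherry"], c(1.5, 0.25, 1))
  # readings before the cutoff may exceed 1 when the global max fell in day 1
  expect_gt(max(out$value), 1)
  # idempotent when the post-cutoff max is already 1
  again <- normalize_after_day1(out)
  expect_equal(again$value, out$value)
  bad <- make_traces(); bad$value[bad$t_h >= 24] <- 0
  expect_error(normalize_after_day1(bad), class = "idcsim_bad_trace")
})

test_that("donor-to-recipient ratios use per-species max normalization", {
  out <- donor_recipient_ratio(c(8, 10, 0), c(2, 10, 5))
  expect_equal(out$ratio[2], 1)          # both at their max
  expect_equal(out$ratio[1], 0.8 / 0.2)  # 4
  expect_equal(out$ratio[3], 0)
  z <- donor_recipient_ratio(c(1, 2), c(4, 0))
  expect_true(is.na(z$ratio[2]))
  expect_true(z$flag_zero_recipient[2])
})

test_that("the log-log GLM recovers exact power laws and excludes detection limits", {
  dr <- c(0.5, 1, 2, 4, 8)
  idc <- 1 / dr  # exact slope -1
  fit <- fit_loglog_glm(dr, idc)
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$n_excluded, 0)
  # rows at the 0.1 floor and 500 cap are dropped and counted
  fit2 <- fit_loglog_glm(c(dr, 1, 1), c(idc, 0.1, 500))
  expect_equal(fit2$n_excluded, 2)
  expect_equal(fit2$n_used, 5)
  expect_error(fit_loglog_glm(c(1, 2), c(1, 2)), class = "idcsim_underpowered")
})

test_that("the GLM equals closed-form least squares", {
  set.seed(3)
  for (rep in 1:4) {
    dr <- 10^runif(7, -1, 2)
    idc <- 10^runif(7, 0, 2.5)
    fit <- fit_loglog_glm(dr, idc)
    # normal-equations oracle
    x <- log10(dr); y <- log10(idc)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  }
})

test_that("daily slopes track a per-day generated trend", {
  set.seed(4)
  dr <- 10^seq(-1, 1, length.out = 8)
  days <- 1:5
  data <- do.call(rbind, lapply(days, function(d) {
    data.frame(day = d, dr = dr, idc = 10^(1.5 - 0.2 * d * log10(dr)))
  }))
  out <- daily_slopes(data)
  expect_equal(out$day, days)
  expect_equal(out$slope, -0.2 * days, tolerance = 1e-8)
  expect_true(all(diff(out$slope) < 0))  # increasingly negative over time
  # identical data each day give identical slopes
  same <- do.call(rbind, lapply(1:3, function(d)
    data.frame(day = d, dr = dr, idc = 10^(1 - log10(dr)) + 0)))
  out2 <- daily_slopes(same)
  expect_equal(out2$slope, rep(out2$slope[1], 3))
  # underpowered days are flagged, not fatal
  mix <- rbind(data, data.frame(day = 9, dr = 1, idc = 10))
  out3 <- daily_slopes(mix)
  expect_equal(out3$flag[out3$day == 9], "underpowered")
})

test_that("fold decrease keeps the published sign convention", {
  expect_equal(fold_decrease(1, 0.5), -2, ignore_attr = TRUE)
  expect_equal(fold_decrease(0.7, 0.7), -1, ignore_attr = TRUE)
  out <- fold_decrease(1, 0)
  expect_true(is.na(out))
  expect_true(attr(out, "flag_zero_coculture"))
})

test_that("CFU conventions: floor, estimate and lawn flags", {
  out <- adjust_cfu(c(0, 37, 250, 600, Inf))
  expect_equal(out$value, c(0, 37, 250, 500, 500))
  expect_equal(out$log_display[1], 0.1)
  expect_true(out$flag_floor[1])
  expect_false(any(out$flag_floor[-1]))
  expect_equal(out$flag_estimate, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$flag_lawn, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # dilution series scales the estimate
  d <- adjust_cfu(c(42), dilution = 100)
  expect_equal(d$estimated_cfu, 4200)
  expect_error(adjust_cfu(-1), class = "idcsim_bad_counts")
})
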