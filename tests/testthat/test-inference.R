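test_that("LHS samples have the Latin property per parameter", {
  ranges <- list(a = c(0, 1), b = list(lo = 1e-6, hi = 1e-2, log = TRUE),
                 c = c(-5, 5))
  n <- 8
  s <- lhs_sample(ranges, n, seed = 4)
  expect_equal(dim(s), c(n, 3))
  # each marginal puts exactly one value in each of n equal strata
  strata_a <- floor(s[, "a"] * n)
  expect_setequal(strata_a, 0:(n - 1))
  lg <- (log10(s[, "b"]) - (-6)) / 4  # unit scale in log space
  expect_setequal(floor(lg * n), 0:(n - 1))
  # degenerate range gives a constant column
  s2 <- lhs_sample(list(a = c(2, 2), b = c(0, 1)), 5, seed = 1)
  expect_equal(s2[, "a"], rep(2, 5))
  # determinism
  expect_identical(lhs_sample(ranges, 16, seed = 9), lhs_sample(ranges, 16, seed = 9))
  expect_error(lhs_sample(list(a = c(1, 0)), 5), class = "idcsim_bad_fitspec")
})

test_that("trajectory error is zero for self-consistent data and Inf on failure", {
  grid <- seq(0, 72, by = 0.5)
  sim <- data.frame(t_h = rep(grid, 2),
                    species = rep(c("x", "y"), each = length(grid)),
                    value = c(exp(grid / 20), 100 + grid))
  # data = model output on the normalized scale
  norm <- function(df) {
    for (sp in unique(df$species)) {
      sel <- df$species == sp
      df$value[sel] <- df$value[sel] / max(df$value[sel & df$t_h >= 24])
    }
    df
  }
  data <- norm(sim)
  expect_lt(trajectory_error(NULL, data, function(p) sim), 1e-10)
  # constant offset delta on one normalized species over m points: m * delta^2
  off <- data
  sel <- off$species == "y"
  m <- sum(sel)
  delta <- 0.03
  off$value[sel] <- off$value[sel] + delta
  expect_equal(trajectory_error(NULL, off, function(p) sim), m * delta^2,
               tolerance = 1e-8)
  expect_identical(trajectory_error(NULL, data, function(p) stop("boom")), Inf)
  expect_error(trajectory_error(NULL, data[0, ], function(p) sim),
               class = "idcsim_bad_fitspec")
})

test_that("iterative LHS fitting shrinks ranges without losing the best sample", {
  # quadratic bowl in two parameters
  err_fn <- function(p) (p["a"] - 0.3)^2 + 10 * (p["b"] - 0.7)^2
  ranges <- list(a = c(0, 1), b = c(0, 1))
  fit <- iterative_lhs_fit(ranges, err_fn, n_samples = 60, n_rounds = 4,
                           keep_fraction = 0.2, seed = 2)
  expect_lt(abs(fit$best_params[["a"]] - 0.3), 0.05)
  expect_lt(abs(fit$best_params[["b"]] - 0.7), 0.02)
  # final ranges never expanded and contain the best vector
  expect_gte(fit$ranges$a$lo, 0); expect_lte(fit$ranges$a$hi, 1)
  expect_gte(fit$best_params[["a"]], fit$ranges$a$lo)
  expect_lte(fit$best_params[["a"]], fit$ranges$a$hi)
  # best error equals the minimum over every scored sample
  all_errs <- unlist(lapply(fit$rounds, function(r) r$error))
  expect_equal(fit$best_error, min(all_errs))
  # one round with keep_fraction 1 is a plain LHS screen: ranges unchanged
  fit1 <- iterative_lhs_fit(ranges, err_fn, n_samples = 30, n_rounds = 1,
                            keep_fraction = 1, seed = 3)
  expect_equal(fit1$ranges$a$lo, 0)
  expect_equal(fit1$ranges$a$hi, 1)
  # all-failure rounds raise a typed error
  expect_error(iterative_lhs_fit(ranges, function(p) Inf, 20, 1, 0.5),
               class = "idcsim_fit_failure")
})

test_that("noise-free generating parameters are a global minimum over samples", {
  err_fn <- function(p) sum((p - c(a = 0.5, b = 0.2))^2)
  fit <- iterative_lhs_fit(list(a = c(0, 1), b = c(0, 1)), err_fn,
                           n_samples = 100, n_rounds = 2, keep_fraction = 0.1,
                           seed = 5)
  truth_err <- err_fn(c(a = 0.5, b = 0.2))
  all_errs <- unlist(lapply(fit$rounds, function(r) r$error))
  expect_true(all(truth_err <= all_errs))
})

test_that("parameter ranking orders by rank-correlation magnitude", {
  set.seed(8)
  n <- 500
  samples <- cbind(p = runif(n), q = runif(n), r = runif(n))
  errors <- samples[, "p"]^3 + 0.01 * rnorm(n)  # monotone in p only
  rk <- rank_parameters(samples, errors)
  expect_equal(rk$parameter[1], "p")
  expect_gt(rk$score[1], 0.9)
  expect_lt(rk$score[rk$parameter == "q"], 0.2)
  expect_lt(rk$score[rk$parameter == "r"], 0.2)
  # alphabetical tie-break for equal sensitivity
  s2 <- cbind(b = c(1:10), a = c(1:10))
  rk2 <- rank_parameters(s2, errors = 1:10)
  expect_equal(rk2$parameter, c("a", "b"))
  expect_warning(rank_parameters(samples, rep(1, n)), "constant")
})
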