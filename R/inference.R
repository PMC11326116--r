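#' Latin hypercube sample of a parameter hypercube
#'
#' Draws `n` parameter vectors such that, for every parameter, the `n` values
#' occupy `n` distinct equal-probability strata (the Latin property).
#' Parameters flagged `log = TRUE` are stratified in log10 space.
#'
#' @param ranges Named list; each element is `list(lo =, hi =, log = FALSE)`
#'   (or a length-2 numeric vector for a linear range).
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; the sample plan is reproducible bit-for-bit.
#' @return Numeric matrix `n x length(ranges)` with parameter columns.
#' @export
lhs_sample <- function(ranges, n, seed = 1) {
  ranges <- normalize_ranges(ranges)
  if (n < 1) abort_idc("n must be >= 1", "bad_fitspec")
  k <- length(ranges)
  set.seed(seed)
  unit <- lhs::randomLHS(n, k)
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, names(ranges)))
  for (j in seq_len(k)) {
    r <- ranges[[j]]
    if (r$log) {
      out[, j] <- 10^(log10(r$lo) + unit[, j] * (log10(r$hi) - log10(r$lo)))
    } else {
      out[, j] <- r$lo + unit[, j] * (r$hi - r$lo)
    }
  }
  out
}

normalize_ranges <- function(ranges) {
  if (is.null(names(ranges)) || any(names(ranges) == "")) {
    abort_idc("ranges must be a named list", "bad_fitspec")
  }
  lapply(ranges, function(r) {
    if (is.numeric(r) && length(r) == 2L) r <- list(lo = r[1], hi = r[2])
    r$log <- isTRUE(r$log)
    if (!is_scalar_number(r$lo) || !is_scalar_number(r$hi)) {
      abort_idc("range bounds must be finite numbers", "bad_fitspec")
    }
    if (r$lo > r$hi) abort_idc("range lo must be <= hi", "bad_fitspec")
    if (r$log && r$lo <= 0) abort_idc("log-scaled range requires lo > 0", "bad_fitspec")
    r
  })
}

#' Sum-of-squares error between simulated and observed normalized traces
#'
#' The observation table is expected to be already normalized (post-day-1,
#' e.g. via [normalize_after_day1()]); the simulated observables are
#' normalized by their per-species maximum after day 1, linearly
#' interpolated onto the data's time grid, and squared differences are summed
#' over species and time points. A simulation failure scores `+Inf` so that
#' failed parameter draws rank last without breaking the Latin structure of a
#' sampling round.
#'
#' @param params Named parameter vector handed to `simulate_fn`.
#' @param data Data frame with columns `t_h`, `species`, `value`: the
#'   normalized target traces (values on the post-day-1 normalized scale).
#' @param simulate_fn Function `params -> data.frame(t_h, species, value)`
#'   producing model observables on any grid covering the data.
#' @param day1_cutoff_h Normalization cutoff (h), default 24.
#' @return Scalar error >= 0, or `Inf` on solver failure.
#' @export
trajectory_error <- function(params, data, simulate_fn, day1_cutoff_h = 24) {
  if (is.null(data) || nrow(data) == 0) abort_idc("empty target data", "bad_fitspec")
  stopifnot(all(c("t_h", "species", "value") %in% names(data)))
  sim <- tryCatch(simulate_fn(params), error = function(e) NULL)
  if (is.null(sim) || nrow(sim) == 0) return(Inf)
  total <- 0
  for (sp in unique(data$species)) {
    d <- data[data$species == sp, ]
    s <- sim[sim$species == sp, ]
    if (nrow(s) < 2) return(Inf)
    s_max <- max(s$value[s$t_h >= day1_cutoff_h])
    if (!is.finite(s_max) || s_max <= 0) return(Inf)
    pred <- stats::approx(s$t_h, s$value / s_max, xout = d$t_h, rule = 2)$y
    total <- total + sum((pred - d$value)^2)
  }
  total
}

#' Iterative Latin hypercube fit
#'
#' Repeats for `n_rounds`: draw an LHS plan over the current ranges, score
#' every sample, keep the best `keep_fraction`, and shrink each parameter
#' range to the keepers' min-max (log-space for log-scaled parameters).
#' Shrinking never expands a range and never excludes the incumbent best
#' vector, which is itself always a keeper.
#'
#' @param ranges Named list of parameter ranges as in [lhs_sample()].
#' @param error_fn Function `named parameter vector -> scalar error`; should
#'   return `Inf` for unusable draws.
#' @param n_samples Samples per round.
#' @param n_rounds Number of rounds.
#' @param keep_fraction Fraction of samples kept per round, in (0, 1].
#' @param seed Integer seed for the sampling plans.
#' @param checks Optional function `best_params -> named logical/character
#'   vector` run on the final best vector (the qualitative-check report:
#'   e.g. supplementation response, steady-state survival, donor:recipient
#'   plausibility).
#' @return Object of class `idc_fit`: list with `best_params`, `best_error`,
#'   `rounds` (per-round data frames of samples and errors), final `ranges`,
#'   `ranking` from [rank_parameters()], and `checks`.
#' @export
iterative_lhs_fit <- function(ranges, error_fn, n_samples = 500, n_rounds = 3,
                              keep_fraction = 0.1, seed = 1, checks = NULL) {
  ranges <- normalize_ranges(ranges)
  if (keep_fraction <= 0 || keep_fraction > 1) {
    abort_idc("keep_fraction must be in (0, 1]", "bad_fitspec")
  }
  best_params <- NULL
  best_error <- Inf
  rounds <- vector("list", n_rounds)
  cur <- ranges
  for (r in seq_len(n_rounds)) {
    samp <- lhs_sample(cur, n_samples, seed = seed + r - 1L)
    errs <- apply(samp, 1, function(row) error_fn(stats::setNames(row, colnames(samp))))
    rounds[[r]] <- data.frame(round = r, samp, error = errs, check.names = FALSE)
    if (all(!is.finite(errs))) {
      abort_idc(sprintf("round %d: every sampled parameter vector failed to score", r),
                "fit_failure")
    }
    i_best <- which.min(errs)
    if (errs[i_best] < best_error) {
      best_error <- errs[i_best]
      best_params <- stats::setNames(samp[i_best, ], colnames(samp))
    }
    if (r < n_rounds) {  # shrink only between rounds
      n_keep <- max(1L, ceiling(keep_fraction * n_samples))
      keep_idx <- order(errs)[seq_len(n_keep)]
      keepers <- samp[keep_idx, , drop = FALSE]
      # incumbent best stays inside the shrunk box
      keepers <- rbind(keepers, best_params)
      for (nm in names(cur)) {
        cur[[nm]]$lo <- max(cur[[nm]]$lo, min(keepers[, nm]))
        cur[[nm]]$hi <- min(cur[[nm]]$hi, max(keepers[, nm]))
      }
    }
  }
  all_rounds <- do.call(rbind, rounds)
  param_cols <- names(ranges)
  ranking <- rank_parameters(all_rounds[, param_cols, drop = FALSE], all_rounds$error)
  structure(
    list(best_params = best_params, best_error = best_error, rounds = rounds,
         ranges = cur, ranking = ranking,
         checks = if (!is.null(checks)) checks(best_params) else NULL),
    class = "idc_fit"
  )
}

#' @export
print.idc_fit <- function(x, ...) {
  cat("<idc_fit>\n  best error:", format(x$best_error), "\n  best parameters:\n")
  print(x$best_params)
  cat("  sensitivity ranking:\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Rank parameters by sensitivity
#'
#' Sensitivity score = magnitude of the Spearman rank correlation between a
#' parameter's sampled values and the achieved errors, over all finite-error
#' samples; sorted descending, ties broken alphabetically by parameter name.
#'
#' @param samples Matrix or data frame of sampled parameter vectors (columns
#'   named by parameter).
#' @param errors Numeric error per sample.
#' @return Data frame `(parameter, score)` ordered by decreasing score.
#' @export
rank_parameters <- function(samples, errors) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 10) abort_idc("need at least 10 scored samples", "bad_fitspec")
  ok <- is.finite(errors)
  if (length(unique(errors[ok])) <= 1L) {
    warning("error vector is constant; all sensitivity scores are 0")
    score <- stats::setNames(rep(0, ncol(samples)), colnames(samples))
  } else {
    score <- apply(samples[ok, , drop = FALSE], 2, function(v) {
      if (stats::sd(v) == 0) return(0)
      abs(stats::cor(v, errors[ok], method = "spearman"))
    })
  }
  out <- data.frame(parameter = colnames(samples), score = unname(score))
  out[order(-out$score, out$parameter), , drop = FALSE]
}
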