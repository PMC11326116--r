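#' Run the batch protocol under the reduced two-population model
#'
#' Integrates [reduced_two_species_derivatives()] (total bacteria, total
#' yeast, no clumping or conjugation) through the daily dilution protocol.
#'
#' @param sys An [idc_system()] (clump and transfer terms are ignored).
#' @param protocol A [batch_protocol()].
#' @param B0,Y0 Inoculum sizes (cells/well).
#' @param sampling_interval_h Output grid spacing (default 1 h; the reduced
#'   model is used inside fitting loops where a coarse grid suffices).
#' @param rtol,atol Solver tolerances.
#' @return Data frame `(t_h, day, species, value)` with species `bacteria`
#'   and `yeast`.
#' @export
run_reduced_protocol <- function(sys, protocol = batch_protocol(),
                                 B0 = 1e7, Y0 = 1e7,
                                 sampling_interval_h = 1,
                                 rtol = 1e-6, atol = 1e-3) {
  media <- sys$media
  state <- c(B = B0, Y = Y0,
             n_L = unname(concentration(media, "L")),
             n_W = unname(concentration(media, "W")),
             n_U = unname(concentration(media, "U")),
             n_H = unname(concentration(media, "H")),
             n_G = media$glucose_gL)
  times <- seq(0, protocol$day_length_h, by = sampling_interval_h)
  qpack <- pack_reduced_parms(sys)
  out_t <- 0; out_B <- state[["B"]]; out_Y <- state[["Y"]]; out_day <- 0L
  for (day in seq_len(protocol$n_days)) {
    seg <- deSolve::lsoda(state, times, func = "idc_reduced_derivs",
                          parms = qpack, dllname = "idcsim",
                          initfunc = "idc_reduced_initmod",
                          rtol = rtol, atol = atol, maxsteps = 1e5)
    if (nrow(seg) < length(times)) {
      abort_idc(sprintf("reduced model: solver failure on day %d", day),
                "solver_failure")
    }
    seg[seg < 0] <- 0
    t0 <- out_t[length(out_t)]
    out_t <- c(out_t, t0 + seg[-1, 1])
    out_B <- c(out_B, seg[-1, "B"]); out_Y <- c(out_Y, seg[-1, "Y"])
    out_day <- c(out_day, rep(day, nrow(seg) - 1L))
    state <- seg[nrow(seg), -1]
    if (day < protocol$n_days) {
      state[c("B", "Y")] <- state[c("B", "Y")] * protocol$carryover_fraction
      fresh <- c(n_L = unname(concentration(media, "L")),
                 n_W = unname(concentration(media, "W")),
                 n_U = unname(concentration(media, "U")),
                 n_H = unname(concentration(media, "H")),
                 n_G = media$glucose_gL)
      nut <- names(fresh)
      state[nut] <- protocol$fresh_fraction * fresh +
        protocol$carryover_fraction * state[nut]
    }
  }
  data.frame(t_h = rep(out_t, 2), day = rep(out_day, 2),
             species = rep(c("bacteria", "yeast"), each = length(out_t)),
             value = c(out_B, out_Y))
}

# centered rolling mean per well/channel/day; plate-reader traces are
# smoothed before max-normalization so the normalizer is not an extreme-value
# statistic. Smoothing is segmented at the daily dilution boundaries so the
# 10x drops are not smeared.
smooth_traces <- function(traces, window = 9L, day_length_h = 24) {
  if (window <= 1L) return(traces)
  seg <- ceiling((traces$t_h - 1e-9) / day_length_h)
  key <- paste(traces$well, traces$channel, seg)
  for (k in unique(key)) {
    sel <- which(key == k)
    sel <- sel[order(traces$t_h[sel])]
    v <- traces$value[sel]
    if (length(v) < window) next
    f <- stats::filter(v, rep(1 / window, window), sides = 2)
    traces$value[sel] <- ifelse(is.na(f), v, as.numeric(f))
  }
  traces
}

# golden-section refinement of a one-parameter fit around its LHS optimum
polish_1d <- function(fit, err_fn, name, range) {
  r <- normalize_ranges(stats::setNames(list(range), name))[[1]]
  best <- fit$best_params[[name]]
  tr <- if (r$log) log10 else identity
  inv <- if (r$log) function(x) 10^x else identity
  span <- (tr(r$hi) - tr(r$lo)) / 10
  lo <- max(tr(r$lo), tr(best) - span)
  hi <- min(tr(r$hi), tr(best) + span)
  opt <- stats::optimize(function(x) err_fn(stats::setNames(inv(x), name)),
                         interval = c(lo, hi), tol = 1e-4)
  if (is.finite(opt$objective) && opt$objective < fit$best_error) {
    fit$best_params[name] <- inv(opt$minimum)
    fit$best_error <- opt$objective
  }
  fit
}

# squared log10 error between predicted and observed absolute counts
count_error <- function(pred, obs) {
  if (length(pred) != length(obs)) return(Inf)
  ok <- is.finite(pred) & is.finite(obs)
  if (!any(ok)) return(Inf)
  sum((log10(pred[ok] + 1) - log10(obs[ok] + 1))^2)
}

#' Qualitative-check report for a fitted parameter set
#'
#' The three experiment-level plausibility checks consulted while iterating
#' the fits: response to amino-acid supplementation (both species grow more
#' at 100% LW than at 0% LW), steady-state survival of both species at the
#' assay media, and a donor-to-recipient ratio within broad plausible bounds.
#'
#' @param params A fitted [model_params()].
#' @param sys Template [idc_system()] supplying genotypes and assay media.
#' @param protocol [batch_protocol()].
#' @param dr_bounds Plausible day-6 donor:recipient ratio interval.
#' @return Named logical vector with elements `supplementation_response`,
#'   `steady_state_survival`, `dr_plausible`.
#' @export
qualitative_checks <- function(params, sys, protocol = batch_protocol(),
                               dr_bounds = c(1e-2, 1e4)) {
  sys$params <- params
  run_at <- function(f) {
    s <- sys
    s$media <- media_config(f_L = f, f_W = f, mannose = sys$media$mannose)
    tryCatch(run_batch_protocol(coculture_state(s$media), s, protocol,
                                rtol = 1e-6, atol = 1e-3)$daily,
             idcsim_error = function(e) NULL)
  }
  lo <- run_at(0); hi <- run_at(1)
  base <- tryCatch(run_batch_protocol(coculture_state(sys$media), sys, protocol,
                                      rtol = 1e-6, atol = 1e-3)$daily,
                   idcsim_error = function(e) NULL)
  n <- function(d) if (is.null(d)) NA_real_ else nrow(d)
  last <- function(d, col) if (is.null(d)) NA_real_ else d[[col]][nrow(d)]
  supp <- isTRUE(last(hi, "B_total") > last(lo, "B_total") &&
                 last(hi, "Y_total") > last(lo, "Y_total"))
  surv <- isTRUE(last(base, "B_total") > 1e4 && last(base, "Y_total") > 1e4)
  dr <- last(base, "B_total") / last(base, "Y_total")
  c(supplementation_response = supp,
    steady_state_survival = surv,
    dr_plausible = isTRUE(dr >= dr_bounds[1] && dr <= dr_bounds[2]))
}

#' Staged Latin hypercube fit of the coculture model
#'
#' Mirrors the staged calibration of the experiments: growth parameters are
#' fit first against mannose-supplemented (clump-free) data using the reduced
#' two-population model, then the free transfer term `gamma` is fit against
#' the mannose CFU counts, and finally the clumped transfer term `gamma_c`
#' against the mannose-free CFU counts with `gamma` held at its stage-2
#' estimate. Fluorescence traces constrain the dynamics (after post-day-1
#' normalization) while the daily flow-like counts anchor absolute scale, as
#' in the dual-measurement design the data emulate.
#'
#' @param traces_mannose Normalized-or-raw coculture traces from the mannose
#'   arm (long format with `t_h`, `channel`, `value`).
#' @param counts_mannose Daily flow counts from the mannose arm
#'   (`day`, `species`, `count`).
#' @param cfu_mannose,cfu_clumped CFU tables ([simulate_cfu_plating()]
#'   columns) from the mannose and mannose-free arms; either a single table
#'   (interpreted at the template media) or a list of `list(cfu =, media =)`
#'   to fit one transfer term jointly across media conditions.
#' @param sys Template [idc_system()]: genotypes, media (the mannose-free
#'   media; the mannose arm is derived from it), and starting parameter set.
#' @param protocol [batch_protocol()].
#' @param growth_ranges Stage-1 ranges (default: a broad window around
#'   typical minimal-media physiology for `mu_B`, `mu_Y`, and log-decade
#'   windows for the limiting consumption coefficients).
#' @param gamma_range,gamma_c_range Log-spaced transfer-term ranges covering
#'   1e-7 to 1e-2 (the literature intraspecies value 4e-3 included).
#' @param n_samples Stage-1 samples per round.
#' @param n_samples_transfer Samples per round for the single-parameter
#'   transfer-term stages.
#' @param n_rounds,keep_fraction Iterated-LHS settings.
#' @param polish After each LHS stage, refine the best vector by a local
#'   search (Nelder-Mead simplex for the growth stage, golden-section for
#'   the one-dimensional transfer stages) — the "adjust" step of an
#'   iterative calibration; removes sampling-resolution scatter (default
#'   `TRUE`).
#' @param seed Integer seed.
#' @param extra_stage1 Optional list of additional mannose-arm conditions for
#'   the stage-1 fit, each a `list(traces =, counts =, media =)`; growth
#'   parameters are then fit jointly across media conditions, as in the
#'   per-pairing calibration the procedure mirrors.
#' @param run_checks Run [qualitative_checks()] on the final parameters.
#' @return Object of class `idc_staged_fit`: list with the three `idc_fit`
#'   stages, the assembled `params`, and `gamma`/`gamma_c` estimates.
#' @export
staged_fit <- function(traces_mannose, counts_mannose, cfu_mannose, cfu_clumped,
                       sys, protocol = batch_protocol(),
                       growth_ranges = list(
                         mu_B = list(lo = 0.1, hi = 1),
                         mu_Y = list(lo = 0.05, hi = 0.8),
                         u_B_L = list(lo = 6e-8, hi = 6e-6, log = TRUE),
                         u_Y_W = list(lo = 1.7e-7, hi = 1.7e-5, log = TRUE)),
                       gamma_range = list(lo = 1e-7, hi = 1e-2, log = TRUE),
                       gamma_c_range = list(lo = 1e-7, hi = 1e-2, log = TRUE),
                       n_samples = 500, n_samples_transfer = 100,
                       n_rounds = 3, keep_fraction = 0.1, polish = TRUE,
                       seed = 1, extra_stage1 = NULL, run_checks = FALSE) {
  sys_man <- sys
  sys_man$media$mannose <- TRUE

  conditions <- c(
    list(list(traces = traces_mannose, counts = counts_mannose,
              media = sys_man$media)),
    extra_stage1)
  conditions <- lapply(conditions, function(cond) {
    # smooth, normalize, and restrict to the post-day-1 window the
    # normalization defines; map channels onto the model's species
    cond$traces <- smooth_traces(cond$traces,
                                 day_length_h = protocol$day_length_h)
    cond$traces <- normalize_after_day1(cond$traces,
                                        day1_cutoff_h = protocol$day_length_h)
    cond$traces <- cond$traces[cond$traces$t_h >= protocol$day_length_h, ]
    cond$traces$species <- ifelse(cond$traces$channel == "mCherry",
                                  "bacteria", "yeast")
    cond$counts <- cond$counts[order(cond$counts$species, cond$counts$day), ]
    cond$media$mannose <- TRUE
    cond
  })

  stage1_error <- function(theta) {
    total <- 0
    for (cond in conditions) {
      s <- sys_man
      s$media <- cond$media
      s$params <- set_params(s$params, as.list(theta))
      sim <- tryCatch(run_reduced_protocol(s, protocol), error = function(e) NULL)
      if (is.null(sim)) return(Inf)
      e_tr <- trajectory_error(theta, cond$traces, function(p) sim)
      # daily totals at end of each day
      ends <- sim[sim$t_h %in% (seq_len(protocol$n_days) * protocol$day_length_h), ]
      ends <- ends[order(ends$species, ends$day), ]
      if (nrow(ends) != nrow(cond$counts)) return(Inf)
      # balance the two data streams: the handful of absolute daily counts is
      # all that anchors absolute abundances (normalized traces cannot), so
      # each stream contributes comparably to the objective
      w <- nrow(cond$traces) / nrow(cond$counts)
      total <- total + e_tr + w * count_error(ends$value, cond$counts$count)
    }
    total
  }
  fit1 <- iterative_lhs_fit(growth_ranges, stage1_error, n_samples, n_rounds,
                            keep_fraction, seed = seed)
  if (polish) {
    # simplex refinement from the LHS optimum, log scale for log-ranged
    # parameters so step sizes are proportionate
    is_log <- vapply(normalize_ranges(growth_ranges), function(r) r$log,
                     logical(1))
    to_opt <- function(p) ifelse(is_log, log10(p), p)
    from_opt <- function(x) stats::setNames(ifelse(is_log, 10^x, x),
                                            names(growth_ranges))
    opt <- stats::optim(to_opt(fit1$best_params),
                        function(x) stage1_error(from_opt(x)),
                        method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-6))
    if (is.finite(opt$value) && opt$value < fit1$best_error) {
      fit1$best_params <- from_opt(opt$par)
      fit1$best_error <- opt$value
    }
  }

  params1 <- set_params(sys$params, as.list(fit1$best_params))

  cfu_target <- function(cfu) {
    usable <- !cfu$flag_lawn
    list(day = cfu$day[usable], obs = cfu$estimated_cfu[usable])
  }
  as_arms <- function(cfu, default_media) {
    if (is.data.frame(cfu)) list(list(cfu = cfu, media = default_media))
    else cfu
  }
  transfer_error <- function(sys_i, arms, fixed = list()) {
    arms <- lapply(arms, function(a) { a$target <- cfu_target(a$cfu); a })
    function(theta) {
      total <- 0
      for (a in arms) {
        s <- sys_i
        s$media <- a$media
        s$params <- set_params(s$params, c(as.list(theta), fixed))
        traj <- tryCatch(
          run_batch_protocol(coculture_state(s$media), s, protocol,
                             rtol = 1e-6, atol = 1e-3),
          idcsim_error = function(e) NULL)
        if (is.null(traj)) return(Inf)
        pred <- traj$daily$expected_cfu[match(a$target$day, traj$daily$day)]
        total <- total + count_error(pred, a$target$obs)
      }
      total
    }
  }

  sys2 <- sys_man; sys2$params <- params1
  arms_man <- lapply(as_arms(cfu_mannose, sys_man$media), function(a) {
    a$media$mannose <- TRUE; a
  })
  err2 <- transfer_error(sys2, arms_man)
  fit2 <- iterative_lhs_fit(list(gamma = gamma_range), err2,
                            n_samples_transfer, n_rounds, keep_fraction,
                            seed = seed + 100L)
  if (polish) fit2 <- polish_1d(fit2, err2, "gamma", gamma_range)
  gamma_hat <- unname(fit2$best_params["gamma"])

  sys3 <- sys; sys3$params <- params1
  arms_clump <- lapply(as_arms(cfu_clumped, sys$media), function(a) {
    a$media$mannose <- FALSE; a
  })
  err3 <- transfer_error(sys3, arms_clump, fixed = list(gamma = gamma_hat))
  fit3 <- iterative_lhs_fit(list(gamma_c = gamma_c_range), err3,
                            n_samples_transfer, n_rounds, keep_fraction,
                            seed = seed + 200L)
  if (polish) fit3 <- polish_1d(fit3, err3, "gamma_c", gamma_c_range)
  gamma_c_hat <- unname(fit3$best_params["gamma_c"])

  params_final <- set_params(params1, list(gamma = gamma_hat,
                                           gamma_c = gamma_c_hat))
  checks <- if (run_checks) qualitative_checks(params_final, sys, protocol)
            else NULL
  structure(
    list(stage1 = fit1, gamma_fit = fit2, gamma_c_fit = fit3,
         params = params_final, gamma = gamma_hat, gamma_c = gamma_c_hat,
         checks = checks),
    class = "idc_staged_fit"
  )
}

#' @export
print.idc_staged_fit <- function(x, ...) {
  cat("<idc_staged_fit>\n")
  cat(sprintf("  gamma   (free):    %.3g\n", x$gamma))
  cat(sprintf("  gamma_c (clumped): %.3g\n", x$gamma_c))
  cat("  stage-1 growth parameters:\n")
  print(x$stage1$best_params)
  if (!is.null(x$checks)) { cat("  checks:\n"); print(x$checks) }
  invisible(x)
}
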