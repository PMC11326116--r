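#' Daily batch-dilution protocol
#'
#' Describes the serial batch culture: wells grow for `day_length_h` hours,
#' are sampled (fluorescence every `sampling_interval_h`, counts and a
#' selective plating at each day boundary), then diluted 1:10 into fresh
#' media (180 uL fresh + 20 uL carryover in a 200 uL well).
#'
#' @param n_days Number of growth days (integer >= 0).
#' @param day_length_h Hours per day (default 24).
#' @param fresh_fraction,carryover_fraction Dilution fractions; must sum to 1.
#' @param sampling_interval_h Output grid spacing (default 0.25 h = 15 min).
#' @param plating_volume_uL Volume plated on selective media (default 100).
#' @param well_volume_uL Culture volume (default 200).
#' @param mannose_switch_day Optional day after which mannose is added to the
#'   media, releasing all clumps and preventing new ones (e.g. 6 means the
#'   switch occurs at the dilution ending day 6).
#' @return Object of class `idc_protocol`.
#' @export
batch_protocol <- function(n_days = 6, day_length_h = 24,
                           fresh_fraction = 0.9, carryover_fraction = 0.1,
                           sampling_interval_h = 0.25,
                           plating_volume_uL = 100, well_volume_uL = 200,
                           mannose_switch_day = NULL) {
  if (abs(fresh_fraction + carryover_fraction - 1) > 1e-12) {
    abort_idc("fresh_fraction + carryover_fraction must equal 1", "bad_protocol")
  }
  if (n_days < 0 || n_days != round(n_days)) {
    abort_idc("n_days must be a non-negative integer", "bad_protocol")
  }
  if (day_length_h <= 0 || sampling_interval_h <= 0) {
    abort_idc("day length and sampling interval must be > 0", "bad_protocol")
  }
  structure(
    list(n_days = as.integer(n_days), day_length_h = day_length_h,
         fresh_fraction = fresh_fraction, carryover_fraction = carryover_fraction,
         sampling_interval_h = sampling_interval_h,
         plating_volume_uL = plating_volume_uL, well_volume_uL = well_volume_uL,
         mannose_switch_day = mannose_switch_day),
    class = "idc_protocol"
  )
}

#' Integrate the coculture ODEs over one growth day
#'
#' Adaptive stiff-capable integration (lsoda) of the full model, reported on
#' a uniform sampling grid. Small solver-induced negatives are clipped to
#' zero and the largest clipped magnitude is recorded in the result.
#'
#' @param state Named state vector ([coculture_state()]).
#' @param sys An [idc_system()].
#' @param duration_h Length of the day (> 0).
#' @param sampling_interval_h Output grid spacing.
#' @param rtol,atol Solver tolerances (defaults 1e-8 relative, 1e-6 absolute
#'   cells).
#' @param compiled Use the compiled right-hand side (default); `FALSE` uses
#'   the reference R implementation (identical by construction, slower).
#' @return List with `times` (h), `states` (matrix, one row per grid point),
#'   and `clip_max` (largest negative magnitude clipped).
#' @export
integrate_day <- function(state, sys, duration_h = 24, sampling_interval_h = 0.25,
                          rtol = 1e-8, atol = 1e-6, compiled = TRUE) {
  if (duration_h <= 0) abort_idc("duration_h must be > 0", "bad_protocol")
  check_state(state)
  times <- seq(0, duration_h, by = sampling_interval_h)
  if (times[length(times)] < duration_h) times <- c(times, duration_h)
  out <- tryCatch(
    if (compiled) {
      deSolve::lsoda(y = unname(state), times = times,
                     func = "idc_derivs", parms = pack_full_parms(sys),
                     dllname = "idcsim", initfunc = "idc_initmod",
                     rtol = rtol, atol = atol, maxsteps = 1e5)
    } else {
      rhs <- compile_rhs(sys)
      deSolve::lsoda(y = unname(state), times = times,
                     func = function(t, y, parms) rhs(t, y),
                     parms = NULL, rtol = rtol, atol = atol, maxsteps = 1e5)
    },
    warning = function(w) {
      abort_idc(sprintf("ODE solver failed: %s", conditionMessage(w)), "solver_failure")
    },
    error = function(e) {
      if (inherits(e, "idcsim_error")) stop(e)
      abort_idc(sprintf("ODE solver failed: %s", conditionMessage(e)), "solver_failure")
    }
  )
  if (nrow(out) < length(times)) {
    abort_idc("ODE solver returned an incomplete trajectory", "solver_failure")
  }
  states <- out[, -1, drop = FALSE]
  colnames(states) <- STATE_NAMES
  clip_max <- max(0, -min(states))
  states[states < 0] <- 0
  list(times = out[, 1], states = states, clip_max = clip_max)
}

#' Dilute a well into fresh media
#'
#' Cells are carried over at `carryover_fraction`; nutrient concentrations
#' become the volume-weighted mix of fresh media and the spent culture. The
#' cumulative conjugation counter `T_cum` is bookkeeping and passes through
#' unchanged.
#'
#' @param state Named state vector.
#' @param fresh_media [media_config()] describing the fresh media.
#' @param fresh_fraction,carryover_fraction Volume fractions summing to 1.
#' @return Diluted state vector.
#' @export
apply_dilution <- function(state, fresh_media, fresh_fraction = 0.9,
                           carryover_fraction = 0.1) {
  if (abs(fresh_fraction + carryover_fraction - 1) > 1e-12) {
    abort_idc("dilution fractions must sum to 1", "bad_protocol")
  }
  out <- state
  out[CELL_NAMES] <- state[CELL_NAMES] * carryover_fraction
  fresh <- c(n_L = unname(concentration(fresh_media, "L")),
             n_W = unname(concentration(fresh_media, "W")),
             n_U = unname(concentration(fresh_media, "U")),
             n_H = unname(concentration(fresh_media, "H")),
             n_G = fresh_media$glucose_gL)
  nut <- names(fresh)
  out[nut] <- fresh_fraction * fresh + carryover_fraction * state[nut]
  out
}

#' Run the daily batch-dilution protocol
#'
#' Alternates [integrate_day()] and [apply_dilution()] for `n_days`, recording
#' the dense trajectory and, at each pre-dilution instant, a daily sample:
#' species totals, transconjugant total, cumulative conjugation events, and
#' the expected selective-plate CFU
#' (`T_total * plating_volume / well_volume`). If the protocol has a
#' `mannose_switch_day`, the dilution ending that day switches the media to
#' mannose and instantaneously releases all clumped cells into the free
#' pools.
#'
#' @param initial Named initial state ([coculture_state()]).
#' @param sys An [idc_system()].
#' @param protocol A [batch_protocol()].
#' @param rtol,atol Solver tolerances passed to [integrate_day()].
#' @return Object of class `idc_trajectory`: list with `time_h`, `day`,
#'   `states` (dense matrix), `daily` (data.frame of DailySample records) and
#'   the protocol used.
#' @export
run_batch_protocol <- function(initial, sys, protocol = batch_protocol(),
                               rtol = 1e-8, atol = 1e-6) {
  stopifnot(inherits(protocol, "idc_protocol"))
  check_state(initial)
  state <- initial
  times_all <- 0
  day_all <- 0L
  states_all <- matrix(initial, nrow = 1, dimnames = list(NULL, STATE_NAMES))
  daily <- vector("list", protocol$n_days)
  clip_max <- 0
  switch_day <- protocol$mannose_switch_day

  for (day in seq_len(protocol$n_days)) {
    seg <- tryCatch(
      integrate_day(state, sys, protocol$day_length_h,
                    protocol$sampling_interval_h, rtol = rtol, atol = atol),
      idcsim_error = function(e) {
        abort_idc(sprintf("day %d: %s", day, conditionMessage(e)), "solver_failure")
      }
    )
    clip_max <- max(clip_max, seg$clip_max)
    t0 <- times_all[length(times_all)]
    keep <- -1L  # drop the duplicated segment start
    times_all <- c(times_all, t0 + seg$times[keep])
    day_all <- c(day_all, rep(day, length(seg$times) - 1L))
    states_all <- rbind(states_all, seg$states[keep, , drop = FALSE])
    state <- seg$states[nrow(seg$states), ]

    # DailySample at the pre-dilution instant
    T_total <- state[["T_f"]] + state[["T_c"]]
    daily[[day]] <- data.frame(
      day = day,
      B_total = state[["B_f"]] + state[["B_c"]],
      Y_total = state[["Y_f"]] + state[["Y_c"]],
      T_total = T_total,
      T_cum = state[["T_cum"]],
      expected_cfu = T_total * protocol$plating_volume_uL / protocol$well_volume_uL,
      mannose = sys$media$mannose,
      dilution = day < protocol$n_days
    )

    if (!is.null(switch_day) && day == switch_day) {
      sys$media$mannose <- TRUE
      # mannose disrupts existing clumps immediately
      state[["B_f"]] <- state[["B_f"]] + state[["B_c"]]; state[["B_c"]] <- 0
      state[["Y_f"]] <- state[["Y_f"]] + state[["Y_c"]]; state[["Y_c"]] <- 0
      state[["T_f"]] <- state[["T_f"]] + state[["T_c"]]; state[["T_c"]] <- 0
    }
    if (day < protocol$n_days) {
      state <- apply_dilution(state, sys$media, protocol$fresh_fraction,
                              protocol$carryover_fraction)
    }
  }

  structure(
    list(time_h = times_all, day = day_all, states = states_all,
         daily = if (protocol$n_days > 0) do.call(rbind, daily) else
           data.frame(day = integer(0)),
         protocol = protocol, clip_max = clip_max),
    class = "idc_trajectory"
  )
}

#' @export
print.idc_trajectory <- function(x, ...) {
  cat(sprintf("<idc_trajectory> %d days, %d time points\n",
              x$protocol$n_days, length(x$time_h)))
  if (nrow(x$daily) > 0) print(x$daily, row.names = FALSE)
  invisible(x)
}

#' Species totals over time from a trajectory
#'
#' @param traj An `idc_trajectory`.
#' @return Data frame with `t_h`, `day`, `B_total`, `Y_total`, `T_total`.
#' @export
trajectory_totals <- function(traj) {
  s <- traj$states
  data.frame(
    t_h = traj$time_h, day = traj$day,
    B_total = s[, "B_f"] + s[, "B_c"],
    Y_total = s[, "Y_f"] + s[, "Y_c"],
    T_total = s[, "T_f"] + s[, "T_c"]
  )
}
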