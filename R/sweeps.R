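# assign a scalar parameter by name, supporting "mu_B"/"death_Y" style names
set_param <- function(params, name, value) {
  scalars <- c("sigma_L", "sigma_W", "sigma_L_basal", "tau_loc", "k_a", "k_d",
               "gamma", "gamma_c", "P", "volume_uL")
  if (name %in% scalars) {
    params[[name]] <- value
  } else if (grepl("^(mu|death)_[BYT]$", name)) {
    parts <- strsplit(name, "_")[[1]]
    params[[parts[1]]][parts[2]] <- value
  } else if (grepl("^u_[BYT]_[LWUHG]$", name)) {
    parts <- strsplit(name, "_")[[1]]
    params$u[[parts[2]]][parts[3]] <- value
  } else if (grepl("^K_[BYT]_[LWUHG]$", name)) {
    parts <- strsplit(name, "_")[[1]]
    params$K[[parts[2]]][parts[3]] <- value
  } else {
    abort_idc(sprintf("unknown parameter name '%s'", name), "bad_params")
  }
  params
}

set_params <- function(params, values) {
  for (nm in names(values)) params <- set_param(params, nm, values[[nm]])
  params
}

#' Sweep one or two model parameters over the batch protocol
#'
#' Runs [run_batch_protocol()] for every grid cell and collects a per-day
#' observable; the heatmap data behind the transfer-term and proximity
#' sweeps. Solver failures in individual cells yield `NA` rows rather than
#' aborting the sweep. Cells whose observable matches a supplied experimental
#' value within a tolerance are flagged (the role of the cyan experimental
#' markers on the published heatmaps).
#'
#' @param sys Base [idc_system()].
#' @param axes Named list of 1 or 2 numeric grids; names are parameter names
#'   (`"gamma"`, `"gamma_c"`, `"P"`, `"k_a"`, `"mu_B"`, ...).
#' @param protocol [batch_protocol()].
#' @param observable One of `"transconjugants_per_plated_volume"` (expected
#'   selective-plate CFU per plating volume), `"species_totals"`, or
#'   `"fluorescence_proxy"` (cell count x per-cell yield).
#' @param initial Optional initial state; defaults to
#'   `coculture_state(sys$media)`.
#' @param match_value,match_tol_log10 Optional experimental value to flag:
#'   cells within `match_tol_log10` decades are marked `matched`.
#' @param yields Per-cell fluorescence yields for the proxy observable.
#' @param rtol,atol Solver tolerances.
#' @return Data frame (class `idc_sweep`) with the axis columns, `day`,
#'   `species` (for totals/fluorescence), `value`, and `matched`.
#' @export
parameter_sweep <- function(sys, axes, protocol = batch_protocol(),
                            observable = c("transconjugants_per_plated_volume",
                                           "species_totals", "fluorescence_proxy"),
                            initial = NULL,
                            match_value = NULL, match_tol_log10 = 0.15,
                            yields = c(B = 1e-6, Y = 5e-6),
                            rtol = 1e-6, atol = 1e-3) {
  observable <- match.arg(observable)
  if (length(axes) < 1 || length(axes) > 2 || is.null(names(axes))) {
    abort_idc("axes must be a named list of 1 or 2 grids", "bad_fitspec")
  }
  if (any(lengths(axes) == 0)) abort_idc("axis grids must be non-empty", "bad_fitspec")
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  initial <- initial %||% coculture_state(sys$media)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- sys
    s$params <- set_params(s$params, as.list(grid[i, , drop = FALSE]))
    traj <- tryCatch(
      run_batch_protocol(initial, s, protocol, rtol = rtol, atol = atol),
      idcsim_error = function(e) NULL
    )
    if (is.null(traj)) {
      out <- data.frame(day = NA_integer_, species = NA_character_,
                        value = NA_real_)
    } else if (observable == "transconjugants_per_plated_volume") {
      out <- data.frame(day = traj$daily$day, species = "T",
                        value = traj$daily$expected_cfu)
    } else {
      d <- traj$daily
      out <- data.frame(
        day = rep(d$day, 3L),
        species = rep(c("B", "Y", "T"), each = nrow(d)),
        value = c(d$B_total, d$Y_total, d$T_total)
      )
      if (observable == "fluorescence_proxy") {
        f <- c(B = unname(yields["B"]), Y = unname(yields["Y"]),
               T = unname(yields["Y"]))
        out$value <- out$value * f[out$species]
      }
    }
    rows[[i]] <- cbind(grid[rep(i, nrow(out)), , drop = FALSE], out,
                       row.names = NULL)
  }
  res <- do.call(rbind, rows)
  res$matched <- if (is.null(match_value)) FALSE else
    is.finite(res$value) & res$value > 0 &
      abs(log10(res$value) - log10(match_value)) <= match_tol_log10
  class(res) <- c("idc_sweep", class(res))
  res
}

#' Rescue-assay phase map over leucine and histidine levels
#'
#' Adapts the clump model to the rescue assay: the recipient is a
#' histidine-auxotrophic yeast, the donor plasmid carries the rescue markers
#' (URA3/HIS3), so transconjugants regain prototrophy and can grow where the
#' recipient cannot. For every `(f_L, f_H)` media cell the 6-day protocol is
#' run and the day-6 recipient+transconjugant total and IDC count are
#' recorded, then classified as `collapse`, `suppressed`, or `rescued` by
#' thresholds on the final yeast total.
#'
#' @param donor Donor genotype (payload is forced to `rescue_markers`).
#' @param recipient Recipient genotype (default histidine auxotroph).
#' @param f_L_grid,f_H_grid Media fraction grids.
#' @param params [model_params()].
#' @param protocol [batch_protocol()].
#' @param f_W,f_U Fixed media fractions for the remaining amino acids.
#' @param collapse_threshold,rescue_threshold Day-6 yeast totals (cells/well)
#'   bounding the three classes.
#' @param rtol,atol Solver tolerances.
#' @return Data frame with `f_L`, `f_H`, `yeast_total`, `T_total`,
#'   `idc_count` (expected CFU per plating volume), and `class`.
#' @export
rescue_phase_map <- function(donor = genotype_preset("E_cross"),
                             recipient = genotype_preset("S_his"),
                             f_L_grid, f_H_grid,
                             params = model_params(),
                             protocol = batch_protocol(),
                             f_W = 1, f_U = 1,
                             collapse_threshold = 1e4,
                             rescue_threshold = 1e7,
                             rtol = 1e-6, atol = 1e-3) {
  donor$payload <- "rescue_markers"
  grid <- expand.grid(f_L = f_L_grid, f_H = f_H_grid, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    media <- media_config(f_L = grid$f_L[i], f_W = f_W, f_U = f_U,
                          f_H = grid$f_H[i])
    sys <- idc_system(params, donor, recipient, media)
    traj <- tryCatch(
      run_batch_protocol(coculture_state(media), sys, protocol,
                         rtol = rtol, atol = atol),
      idcsim_error = function(e) NULL
    )
    if (is.null(traj) || nrow(traj$daily) == 0) {
      res[[i]] <- data.frame(grid[i, ], yeast_total = NA_real_,
                             T_total = NA_real_, idc_count = NA_real_,
                             class = NA_character_)
      next
    }
    last <- traj$daily[nrow(traj$daily), ]
    total <- last$Y_total + last$T_total
    cls <- if (total < collapse_threshold) "collapse"
           else if (total >= rescue_threshold) "rescued"
           else "suppressed"
    res[[i]] <- data.frame(grid[i, ], yeast_total = total,
                           T_total = last$T_total,
                           idc_count = last$expected_cfu, class = cls)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
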