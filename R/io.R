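CONFIG_DEFAULTS <- list(
  seed = 1L,
  log_level = "info",
  media = list(f_L = 0.15, f_W = 0.15, f_U = 1, f_H = 1,
               glucose_gL = 20, mannose = FALSE),
  genotypes = list(donor = "E_cross", recipient = "S_cross",
                   donor_mode = "cis", payload = "none"),
  params = list(),
  protocol = list(n_days = 6L, day_length_h = 24, fresh_fraction = 0.9,
                  carryover_fraction = 0.1, sampling_interval_h = 0.25,
                  plating_volume_uL = 100, well_volume_uL = 200,
                  mannose_switch_day = NULL),
  fit = list(n_samples = 500L, n_rounds = 3L, keep_fraction = 0.1),
  synth = list(cv = 0.05, count_sampling = "poisson")
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (with their location),
#' fills defaults (24 h days, 6 days, per-total-cell collision
#' normalization, crossfeeder pairing at 15% LW), and validates ranges.
#'
#' @param path Path to a YAML file; or a list to validate directly.
#' @return Object of class `idc_config`: the fully resolved configuration.
#' @seealso [config_system()] to turn a configuration into a simulatable
#'   system and protocol.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) abort_idc(sprintf("config file not found: %s", path), "io")
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  resolved <- merge_config(CONFIG_DEFAULTS, cfg, "config")
  # validation with key locations
  m <- resolved$media
  for (k in c("f_L", "f_W", "f_U", "f_H")) {
    if (!is.numeric(m[[k]]) || m[[k]] < 0 || m[[k]] > 10) {
      abort_idc(sprintf("config: media.%s must be a number in [0, 10]", k),
                "bad_config")
    }
  }
  if (!is.numeric(resolved$protocol$n_days) || resolved$protocol$n_days < 0) {
    abort_idc("config: protocol.n_days must be a non-negative integer", "bad_config")
  }
  if (!resolved$genotypes$donor %in% c("E", "E_cross")) {
    abort_idc("config: genotypes.donor must be 'E' or 'E_cross'", "bad_config")
  }
  kf <- resolved$fit$keep_fraction
  if (!is.numeric(kf) || kf <= 0 || kf > 1) {
    abort_idc("config: fit.keep_fraction must be in (0, 1]", "bad_config")
  }
  structure(resolved, class = "idc_config")
}

merge_config <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort_idc(sprintf("unknown configuration key(s) at %s: %s", where,
                      paste(unknown, collapse = ", ")), "bad_config")
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) && k != "params") {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]] %||% list(),
                                    paste(where, k, sep = "."))
    } else {
      defaults[k] <- list(user[[k]])
    }
  }
  defaults
}

#' Build the simulatable pieces from a configuration
#'
#' @param config An `idc_config` from [load_config()].
#' @return List with `sys` ([idc_system()]), `protocol`
#'   ([batch_protocol()]), `state` (initial [coculture_state()]), and the
#'   resolved `config`.
#' @export
config_system <- function(config) {
  stopifnot(inherits(config, "idc_config"))
  media <- do.call(media_config, config$media)
  params <- set_params(do.call(model_params, list()), config$params)
  donor <- genotype_preset(config$genotypes$donor,
                           donor_mode = config$genotypes$donor_mode,
                           payload = config$genotypes$payload)
  recipient <- genotype_preset(config$genotypes$recipient)
  pr <- config$protocol
  protocol <- batch_protocol(pr$n_days, pr$day_length_h, pr$fresh_fraction,
                             pr$carryover_fraction, pr$sampling_interval_h,
                             pr$plating_volume_uL, pr$well_volume_uL,
                             pr$mannose_switch_day)
  sys <- idc_system(params, donor, recipient, media)
  list(sys = sys, protocol = protocol, state = coculture_state(media),
       config = config)
}

#' Read a long-format plate-trace CSV
#'
#' Expected header: `well, t_h, channel, value` with an optional
#' `culture_type` column. Malformed rows are reported with their row number.
#'
#' @param path CSV path.
#' @return Data frame of traces.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) abort_idc(sprintf("file not found: %s", path), "io")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_idc(
                   sprintf("cannot parse %s: %s", path, conditionMessage(e)), "io"))
  need <- c("well", "t_h", "channel", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort_idc(sprintf("%s: missing column(s) %s", path,
                      paste(missing_cols, collapse = ", ")), "io")
  }
  for (col in c("t_h", "value")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      abort_idc(sprintf("%s: non-numeric %s at data row %d", path, col, bad[1]), "io")
    }
    df[[col]] <- v
  }
  df
}

#' Write plate traces as long-format CSV
#'
#' @param traces Data frame with the [read_timeseries()] columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(traces, path) {
  stopifnot(all(c("well", "t_h", "channel", "value") %in% names(traces)))
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory as tidy CSVs
#'
#' Writes the dense trajectory in long format `(day, t_h, compartment,
#' value)` and, if `daily_path` is given, the daily samples.
#'
#' @param traj An `idc_trajectory`.
#' @param path Trajectory CSV path.
#' @param daily_path Optional DailySample CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, daily_path = NULL) {
  s <- traj$states
  long <- data.frame(
    day = rep(traj$day, ncol(s)),
    t_h = rep(traj$time_h, ncol(s)),
    compartment = rep(colnames(s), each = nrow(s)),
    value = as.vector(s)
  )
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(daily_path)) {
    utils::write.csv(traj$daily, daily_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write / read a two-channel image pair as 16-bit TIFF
#'
#' The two channels are stored as two pages (directories) of one TIFF.
#'
#' @param pair An `idc_image_pair` (or list with matrices `a`, `b` in
#'   \[0, 1\]).
#' @param path TIFF path.
#' @return `write_image_pair` returns `path` invisibly; `read_image_pair`
#'   an `idc_image_pair`.
#' @export
write_image_pair <- function(pair, path) {
  tiff::writeTIFF(list(pair$a, pair$b), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(path) {
  if (!file.exists(path)) abort_idc(sprintf("file not found: %s", path), "io")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) {
    abort_idc("expected a two-channel (two-page) TIFF", "bad_image")
  }
  structure(list(a = pages[[1]], b = pages[[2]], spec = list(path = path)),
            class = "idc_image_pair")
}
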