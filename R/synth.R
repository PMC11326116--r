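#' Measurement noise model for synthetic data
#'
#' Fluorescence readings get multiplicative lognormal noise with the given
#' coefficient of variation (mean-one multiplier); CFU platings are Poisson
#' sampled. Both stand in for plate-reader and plating noise, for which the
#' experiments report no explicit model.
#'
#' @param cv Lognormal coefficient of variation (default 0.05).
#' @param yields Per-cell fluorescence yield by channel (arbitrary
#'   units/cell).
#' @param count_sampling `"poisson"` or `"none"` for CFU platings.
#' @param seed Integer seed; a fixed seed reproduces the dataset exactly.
#' @return Object of class `idc_noise`.
#' @export
noise_model <- function(cv = 0.05,
                        yields = c(mCherry = 1e-6, ymCitrine = 5e-6, yeBFP = 5e-6),
                        count_sampling = c("poisson", "none"),
                        seed = 1) {
  count_sampling <- match.arg(count_sampling)
  if (cv < 0) abort_idc("cv must be >= 0", "bad_noise")
  structure(list(cv = cv, yields = yields, count_sampling = count_sampling,
                 seed = as.integer(seed)), class = "idc_noise")
}

lognorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)  # mean exactly 1
}

#' Synthetic plate-reader traces from a simulated trajectory
#'
#' Channel readings are per-cell yield times the species total on the
#' trajectory's sampling grid, with multiplicative lognormal noise:
#' mCherry reports total bacteria, ymCitrine total yeast including
#' transconjugants, and (optionally) yeBFP the recipients still carrying the
#' intact target plasmid.
#'
#' @param traj An `idc_trajectory`.
#' @param noise A [noise_model()].
#' @param well Well identifier for the output table.
#' @param culture_type `"coculture"` or `"monoculture"`.
#' @param channels Channels to emit.
#' @return Long data frame `(well, t_h, channel, value, culture_type)`.
#' @export
simulate_plate_traces <- function(traj, noise = noise_model(), well = "A1",
                                  culture_type = "coculture",
                                  channels = c("mCherry", "ymCitrine")) {
  tot <- trajectory_totals(traj)
  set.seed(noise$seed)
  rows <- lapply(channels, function(ch) {
    signal <- switch(ch,
      mCherry = noise$yields[["mCherry"]] * tot$B_total,
      ymCitrine = noise$yields[["ymCitrine"]] * (tot$Y_total + tot$T_total),
      yeBFP = noise$yields[["yeBFP"]] * tot$Y_total,
      abort_idc(sprintf("unknown channel '%s'", ch), "bad_trace"))
    data.frame(well = well, t_h = tot$t_h, channel = ch,
               value = signal * lognorm_mult(nrow(tot), noise$cv),
               culture_type = culture_type)
  })
  do.call(rbind, rows)
}

#' Synthetic selective-plate CFU records from daily transconjugant totals
#'
#' 100 uL of the 200 uL well is plated, so the expected plated cells are half
#' the well total. When a dilution series is supplied, the smallest dilution
#' bringing the expectation under the 500-colony lawn cap is used and the
#' estimated CFU is count x dilution (the convention used when counts
#' saturate undiluted plates). Counts are Poisson draws around the
#' expectation unless sampling is disabled.
#'
#' @param t_totals Daily transconjugant totals (cells/well), one per day.
#' @param noise [noise_model()]; only `count_sampling` and `seed` are used.
#' @param plating_fraction Plated volume / well volume (default 0.5).
#' @param dilutions Available dilution factors (default undiluted only, as in
#'   the routine daily platings).
#' @return Data frame: one row per day with the [adjust_cfu()] columns.
#' @export
simulate_cfu_plating <- function(t_totals, noise = noise_model(),
                                 plating_fraction = 0.5, dilutions = 1) {
  if (any(t_totals < 0)) abort_idc("transconjugant totals must be >= 0", "bad_counts")
  set.seed(noise$seed + 1L)
  dilutions <- sort(dilutions)
  expected <- t_totals * plating_fraction
  n <- length(expected)
  dil <- numeric(n); raw <- numeric(n)
  for (i in seq_len(n)) {
    ok <- dilutions[expected[i] / dilutions < 500]
    d <- if (length(ok)) ok[1] else dilutions[length(dilutions)]
    lambda <- expected[i] / d
    cnt <- if (lambda >= 500) Inf
           else if (noise$count_sampling == "poisson") stats::rpois(1, lambda)
           else round(lambda)
    dil[i] <- d; raw[i] <- cnt
  }
  out <- adjust_cfu(raw, dilution = dil)
  cbind(day = seq_len(n), out)
}

#' Synthetic two-channel colony image pair with tunable colocalization
#'
#' Builds a base texture (random Gaussian blobs or angular sectors) and a
#' second channel mixing the base with an independent texture according to
#' the colocalization parameter `rho`: `rho = 1` duplicates the structure
#' (ICQ = 0.5), `rho = -1` produces the complementary image (ICQ = -0.5),
#' and `rho = 0` gives an independent channel (ICQ near 0); the expected ICQ
#' is monotone in `rho`.
#'
#' @param size Raster side length in pixels.
#' @param pattern `"gaussian_blobs"` or `"sectors"`.
#' @param rho Colocalization parameter in \[-1, 1\].
#' @param seed Integer seed.
#' @param intensity Peak intensity scale in \[0, 1\].
#' @return Object of class `idc_image_pair`: list with matrices `a`, `b`
#'   (values in \[0, 1\]) and the generating spec.
#' @export
generate_colony_image_pair <- function(size = 256,
                                       pattern = c("gaussian_blobs", "sectors"),
                                       rho = 0, seed = 1, intensity = 0.8) {
  pattern <- match.arg(pattern)
  if (rho < -1 || rho > 1) abort_idc("rho must be in [-1, 1]", "bad_image")
  set.seed(seed)
  base <- colony_texture(size, pattern)
  indep <- colony_texture(size, pattern)
  b <- if (rho >= 0) rho * base + (1 - rho) * indep
       else (-rho) * (max(base) - base) + (1 + rho) * indep
  scale01 <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) return(m * 0)
    intensity * (m - rng[1]) / diff(rng)
  }
  structure(list(a = scale01(base), b = scale01(b),
                 spec = list(size = size, pattern = pattern, rho = rho,
                             seed = seed)),
            class = "idc_image_pair")
}

colony_texture <- function(size, pattern) {
  xy <- seq_len(size)
  if (pattern == "gaussian_blobs") {
    m <- matrix(0, size, size)
    n_blobs <- 40
    cx <- stats::runif(n_blobs, 1, size)
    cy <- stats::runif(n_blobs, 1, size)
    w <- stats::runif(n_blobs, size / 40, size / 8)
    amp <- stats::runif(n_blobs, 0.3, 1)
    for (k in seq_len(n_blobs)) {
      gx <- exp(-(xy - cx[k])^2 / (2 * w[k]^2))
      gy <- exp(-(xy - cy[k])^2 / (2 * w[k]^2))
      m <- m + amp[k] * outer(gx, gy)
    }
  } else {
    ctr <- (size + 1) / 2
    theta <- atan2(outer(xy - ctr, rep(1, size)), outer(rep(1, size), xy - ctr))
    n_sec <- 12
    lev <- stats::runif(n_sec)
    idx <- pmin(n_sec, 1 + floor((theta + pi) / (2 * pi) * n_sec))
    r <- sqrt(outer((xy - ctr)^2, rep(1, size)) + outer(rep(1, size), (xy - ctr)^2))
    m <- matrix(lev[idx], size, size) * exp(-(r / (0.6 * size))^2)
  }
  # continuous jitter breaks exact intensity ties
  m + matrix(stats::rnorm(size^2, sd = 1e-3 * max(m)), size, size)
}

#' Joint sweep of colony colocalization and clump-mediated IDC
#'
#' Emulates the experimental comparison of spatial intermixing and IDC: each
#' coupling level sets both the colony colocalization (`rho = level`) and the
#' clump association rate (`k_a = level * k_a_base`), so stronger physical
#' association produces both higher ICQ and, through the clumped transfer
#' term, more transconjugants.
#'
#' @param levels Coupling levels in \[0, 1\] (default 7 evenly spaced).
#' @param sys Base [idc_system()].
#' @param protocol [batch_protocol()].
#' @param seed Integer seed for the image pairs.
#' @param image_size Raster side for the colony images.
#' @return Data frame `(level, rho, icq, idc_day_final)`.
#' @export
simulate_colocalization_sweep <- function(levels = seq(0, 1, length.out = 7),
                                          sys = idc_system(),
                                          protocol = batch_protocol(),
                                          seed = 1, image_size = 128) {
  k_a_base <- sys$params$k_a
  rows <- lapply(seq_along(levels), function(i) {
    lev <- levels[i]
    pair <- generate_colony_image_pair(size = image_size, rho = lev,
                                       seed = seed + i)
    s <- sys
    s$params$k_a <- lev * k_a_base
    traj <- run_batch_protocol(coculture_state(s$media), s, protocol,
                               rtol = 1e-6, atol = 1e-3)
    data.frame(level = lev, rho = lev, icq = compute_icq(pair),
               idc_day_final = traj$daily$expected_cfu[nrow(traj$daily)])
  })
  do.call(rbind, rows)
}

#' Generate the full synthetic pseudo-experiment
#'
#' The dataset every downstream stage consumes: for each cell pairing, media
#' %LW level and mannose state, a 6-day batch trajectory with plate-reader
#' traces (coculture plus both monoculture companions), daily flow-like
#' counts, and selective-plate CFU records with a dilution series; plus
#' colony image pairs over a grid of colocalization levels. The manifest
#' records every generator ground truth (including the transfer terms
#' gamma = 2e-5 and gamma_c = 3e-4 of the default parameter set) for
#' recovery tests.
#'
#' @param master_seed Integer seed controlling every random draw.
#' @param pairings Character vector of `"donor:recipient"` preset pairs.
#' @param lw_levels %LW media fractions.
#' @param mannose Logical vector of mannose states to generate.
#' @param params Ground-truth [model_params()].
#' @param protocol [batch_protocol()].
#' @param noise_cv Fluorescence noise CV.
#' @param rho_levels Colocalization levels for the colony images (default 7).
#' @param out_dir Optional directory: writes traces/counts/CFU CSVs, TIFF
#'   image pairs, and `manifest.json`.
#' @return List with `traces`, `counts`, `cfu` (data frames), `images`
#'   (list of `idc_image_pair`), and `manifest`.
#' @export
make_fixture_suite <- function(master_seed = 1,
                               pairings = c("E:S", "E_cross:S", "E:S_cross",
                                            "E_cross:S_cross"),
                               lw_levels = c(0, 0.05, 0.10, 0.15),
                               mannose = c(FALSE, TRUE),
                               params = model_params(),
                               protocol = batch_protocol(),
                               noise_cv = 0.05,
                               rho_levels = seq(-1, 1, length.out = 7),
                               out_dir = NULL) {
  traces <- list(); counts <- list(); cfu <- list(); runs <- list()
  run_id <- 0L
  for (pairing in pairings) {
    parts <- strsplit(pairing, ":", fixed = TRUE)[[1]]
    for (lw in lw_levels) for (mn in mannose) {
      run_id <- run_id + 1L
      seed_i <- master_seed + 1000L * run_id
      media <- media_config(f_L = lw, f_W = lw, mannose = mn)
      sys <- idc_system(params, genotype_preset(parts[1]),
                        genotype_preset(parts[2]), media)
      well <- sprintf("%s_lw%g_%s", gsub(":", "-", pairing), 100 * lw,
                      if (mn) "man" else "noman")
      traj <- run_batch_protocol(coculture_state(media), sys, protocol,
                                 rtol = 1e-6, atol = 1e-3)
      nm <- noise_model(cv = noise_cv, seed = seed_i)
      tr <- simulate_plate_traces(traj, nm, well = well)
      # monoculture companions: rerun with one species absent
      mono_B <- run_batch_protocol(coculture_state(media, Y = 0), sys, protocol,
                                   rtol = 1e-6, atol = 1e-3)
      mono_Y <- run_batch_protocol(coculture_state(media, B = 0), sys, protocol,
                                   rtol = 1e-6, atol = 1e-3)
      tr <- rbind(
        tr,
        simulate_plate_traces(mono_B, noise_model(cv = noise_cv, seed = seed_i + 1L),
                              well = paste0(well, "_monoB"),
                              culture_type = "monoculture",
                              channels = "mCherry"),
        simulate_plate_traces(mono_Y, noise_model(cv = noise_cv, seed = seed_i + 2L),
                              well = paste0(well, "_monoY"),
                              culture_type = "monoculture",
                              channels = "ymCitrine"))
      set.seed(seed_i + 3L)
      cnt <- data.frame(
        well = well, day = rep(traj$daily$day, 2),
        species = rep(c("bacteria", "yeast"), each = nrow(traj$daily)),
        count = c(traj$daily$B_total * lognorm_mult(nrow(traj$daily), noise_cv),
                  (traj$daily$Y_total + traj$daily$T_total) *
                    lognorm_mult(nrow(traj$daily), noise_cv)),
        source = "flow")
      cf <- cbind(well = well,
                  simulate_cfu_plating(traj$daily$T_total,
                                       noise_model(seed = seed_i + 4L),
                                       dilutions = 10^(0:4)))
      traces[[well]] <- tr; counts[[well]] <- cnt; cfu[[well]] <- cf
      runs[[well]] <- list(well = well, pairing = pairing, lw = lw,
                           mannose = mn, seed = seed_i)
    }
  }
  images <- lapply(seq_along(rho_levels), function(i) {
    generate_colony_image_pair(rho = rho_levels[i], seed = master_seed + i)
  })
  names(images) <- sprintf("rho_%+.2f", rho_levels)
  manifest <- list(
    master_seed = master_seed,
    ground_truth = list(gamma = params$gamma, gamma_c = params$gamma_c,
                        P = params$P, k_a = params$k_a, k_d = params$k_d,
                        mu = as.list(params$mu), noise_cv = noise_cv),
    runs = unname(runs),
    images = lapply(images, function(im) im$spec)
  )
  out <- list(traces = do.call(rbind, c(traces, list(make.row.names = FALSE))),
              counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
              cfu = do.call(rbind, c(cfu, list(make.row.names = FALSE))),
              images = images, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_timeseries(out$traces, file.path(out_dir, "traces.csv"))
    utils::write.csv(out$counts, file.path(out_dir, "counts.csv"),
                     row.names = FALSE)
    utils::write.csv(out$cfu, file.path(out_dir, "cfu.csv"), row.names = FALSE)
    for (nm in names(images)) {
      write_image_pair(images[[nm]], file.path(out_dir, paste0(nm, ".tiff")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
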