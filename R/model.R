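#' Monod saturation factor
#'
#' Saturating dependence of growth on a limiting nutrient. Populations that do
#' not require the nutrient (prototrophs) get a factor of exactly 1.
#'
#' @param conc Nutrient concentration (uM, or g/L for glucose), >= 0.
#' @param K Half-saturation constant in the same units, > 0.
#' @param required Logical; does this population require the nutrient?
#' @return `conc / (K + conc)` if required, otherwise 1.
#' @export
monod_factor <- function(conc, K, required = TRUE) {
  if (any(K <= 0)) abort_idc("Monod constant K must be > 0", "bad_params")
  if (any(conc < 0)) abort_idc("concentration must be >= 0", "bad_state")
  ifelse(required, conc / (K + conc), 1)
}

#' Nutrient concentration perceived by a (possibly clumped) cell
#'
#' Free cells see only the bulk well-average concentration. Cells clumped to
#' secreting partners additionally see a local standing concentration
#' `P * sigma * partners * tau_loc`: the proximity multiplier `P` scales the
#' benefit of partner secretion irrespective of the basal secretion rate.
#'
#' @param bulk Bulk concentration (uM).
#' @param P Proximity multiplier (dimensionless).
#' @param sigma Partner per-cell secretion rate (uM/h/cell).
#' @param partners Number of secreting partner cells in the clumped pool.
#' @param tau_loc Residence factor (h).
#' @param clumped Logical.
#' @return Effective concentration in uM.
#' @export
effective_concentration <- function(bulk, P, sigma, partners, tau_loc, clumped) {
  if (any(c(bulk, P, sigma, partners, tau_loc) < 0)) {
    abort_idc("effective_concentration inputs must be >= 0", "bad_state")
  }
  if (clumped) bulk + P * sigma * partners * tau_loc else bulk
}

#' Conjugative transfer rate
#'
#' The transfer term `gamma` is the fractional occurrence of conjugative
#' transfer per donor-recipient collision per hour. Under the default
#' `per_total_cell` collision normalization the rate of new transconjugants is
#' `gamma * D * R / (D + R + bystanders)`; with 1000 donors, 1000 recipients
#' and the literature intraspecies value `gamma = 0.004` this yields 2 new
#' transconjugants per hour. The `mass_action_density` mode is the classic
#' Levin-style form `gamma * D * R / volume` (with `gamma` then in
#' uL/cell/h).
#'
#' @param donors,recipients,bystanders Cell counts (>= 0). Bystanders enter
#'   only the collision normalization, not the transfer itself.
#' @param gamma Transfer term (>= 0).
#' @param mode `"per_total_cell"` or `"mass_action_density"`.
#' @param volume_uL Well volume, used by the mass-action mode.
#' @return New transconjugants per hour (0 whenever donors or recipients are 0).
#' @export
conjugation_rate <- function(donors, recipients, bystanders = 0, gamma,
                             mode = c("per_total_cell", "mass_action_density"),
                             volume_uL = 200) {
  mode <- match.arg(mode)
  if (any(c(donors, recipients, bystanders, gamma) < 0)) {
    abort_idc("conjugation_rate inputs must be >= 0", "bad_state")
  }
  if (donors == 0 || recipients == 0) return(0)
  if (mode == "per_total_cell") {
    n_tot <- donors + recipients + bystanders
    if (n_tot == 0) return(0)
    gamma * donors * recipients / n_tot
  } else {
    gamma * donors * recipients / volume_uL
  }
}

# Precompute everything the right-hand side needs from an idc_system, so the
# inner ODE function stays allocation-light. Returns function(t, y) -> list.
compile_rhs <- function(sys) {
  p <- sys$params
  mu <- p$mu; death <- p$death
  req <- sys$req
  KB <- p$K$B; KY <- p$K$Y; KT <- p$K$T
  uB <- p$u$B; uY <- p$u$Y; uT <- p$u$T
  aa <- c("L", "W", "U", "H")
  reqB_i <- match(req$B, aa); reqY_i <- match(req$Y, aa); reqT_i <- match(req$T, aa)
  sec_Y_L <- if ("L" %in% sys$recipient$overproduces) p$sigma_L else
    if (sys$recipient$species == "yeast") p$sigma_L_basal else 0
  sec_B_W <- if ("W" %in% sys$donor$overproduces) p$sigma_W else 0
  donor_active <- sys$donor$donor_mode != "none" &&
    sys$donor$payload != "crispr_no_oriT"
  g_f <- if (donor_active) p$gamma else 0
  g_c <- if (donor_active) p$gamma_c else 0
  ka <- if (sys$media$mannose) 0 else p$k_a
  kd <- p$k_d
  per_total <- p$collision_norm == "per_total_cell"
  vol <- p$volume_uL
  P <- p$P; tau <- p$tau_loc
  boost_L <- "L" %in% req$B && sec_Y_L > 0  # only L is yeast-secreted
  KB_aa <- KB[aa]; KY_aa <- KY[aa]; KT_aa <- KT[aa]

  function(t, y) {
    y[y < 0] <- 0
    B_f <- y[1L]; B_c <- y[2L]; Y_f <- y[3L]; Y_c <- y[4L]
    T_f <- y[5L]; T_c <- y[6L]
    n <- y[7:10]; n_G <- y[11L]

    # effective nutrients for clumped bacteria (proximity benefit)
    n_eff <- n
    if (boost_L) n_eff[1L] <- n[1L] + P * sec_Y_L * (Y_c + T_c) * tau

    mG_B <- n_G / (KB[5L] + n_G)
    mG_Y <- n_G / (KY[5L] + n_G)
    mG_T <- n_G / (KT[5L] + n_G)

    fB_f <- mG_B; fB_c <- mG_B
    for (i in reqB_i) {
      fB_f <- fB_f * n[i] / (KB_aa[i] + n[i])
      fB_c <- fB_c * n_eff[i] / (KB_aa[i] + n_eff[i])
    }
    fY <- mG_Y
    for (i in reqY_i) fY <- fY * n[i] / (KY_aa[i] + n[i])
    fT <- mG_T
    for (i in reqT_i) fT <- fT * n[i] / (KT_aa[i] + n[i])

    gB_f <- mu[1L] * fB_f; gB_c <- mu[1L] * fB_c
    gY <- mu[2L] * fY; gT <- mu[3L] * fT

    # clump exchange: free cells adsorb to the partner species (mass action),
    # so multiple bacteria may coat one yeast; totals per population conserved
    partner_Y <- Y_f + Y_c + T_f + T_c
    partner_B <- B_f + B_c
    assoc_B <- ka * B_f * partner_Y
    assoc_Y <- ka * partner_B * Y_f
    assoc_T <- ka * partner_B * T_f

    # conjugation within each compartment; transconjugants never donate
    rate_f <- 0; rate_c <- 0
    if (g_f > 0 && B_f > 0 && Y_f > 0) {
      rate_f <- if (per_total) g_f * B_f * Y_f / (B_f + Y_f + T_f)
                else g_f * B_f * Y_f / vol
    }
    if (g_c > 0 && B_c > 0 && Y_c > 0) {
      rate_c <- if (per_total) g_c * B_c * Y_c / (B_c + Y_c + T_c)
                else g_c * B_c * Y_c / vol
    }

    # nutrient fluxes: secretion by overproducers, growth-coupled consumption
    dn <- c(sec_Y_L * (Y_f + Y_c + T_f + T_c), sec_B_W * (B_f + B_c), 0, 0)
    for (i in reqB_i) {
      # clumped cells draw the locally-supplied share from partner secretion,
      # not the bulk pool (bulk share = n / n_eff)
      share <- if (n_eff[i] > 0) n[i] / n_eff[i] else 0
      dn[i] <- dn[i] - uB[i] * (gB_f * B_f + gB_c * B_c * share)
    }
    for (i in reqY_i) dn[i] <- dn[i] - uY[i] * gY * (Y_f + Y_c)
    for (i in reqT_i) dn[i] <- dn[i] - uT[i] * gT * (T_f + T_c)
    dn_G <- -(uB[5L] * (gB_f * B_f + gB_c * B_c) +
              uY[5L] * gY * (Y_f + Y_c) + uT[5L] * gT * (T_f + T_c))

    list(c(
      gB_f * B_f - death[1L] * B_f - assoc_B + kd * B_c,
      gB_c * B_c - death[1L] * B_c + assoc_B - kd * B_c,
      gY * Y_f - death[2L] * Y_f - assoc_Y + kd * Y_c - rate_f,
      gY * Y_c - death[2L] * Y_c + assoc_Y - kd * Y_c - rate_c,
      gT * T_f - death[3L] * T_f - assoc_T + kd * T_c + rate_f,
      gT * T_c - death[3L] * T_c + assoc_T - kd * T_c + rate_c,
      dn, dn_G,
      rate_f + rate_c
    ))
  }
}

#' Time derivatives of the full coculture state
#'
#' Implements the deterministic model: multiplicative Monod growth on required
#' nutrients and glucose, first-order death, per-cell constant secretion by
#' overproducers, growth-coupled consumption, reversible mass-action
#' bacterium-yeast clump exchange (association suppressed by mannose; several
#' bacteria may adsorb to one yeast), proximity-boosted
#' nutrient access for clumped bacteria, and conjugative transfer moving
#' recipients to transconjugants within each compartment (free term `gamma`,
#' clumped term `gamma_c`). Transconjugants never donate.
#'
#' @param state Named state vector as returned by [coculture_state()].
#' @param sys An [idc_system()].
#' @param t Time (h); the system is autonomous, `t` is accepted for interface
#'   compatibility.
#' @return Named vector of time derivatives, same shape as `state`.
#' @export
coculture_derivatives <- function(state, sys, t = 0) {
  stopifnot(inherits(sys, "idc_system"))
  check_state(state)
  rhs <- compile_rhs(sys)
  d <- rhs(t, state)[[1]]
  names(d) <- STATE_NAMES
  d
}

check_state <- function(state, tol = 1e-6) {
  if (length(state) != length(STATE_NAMES)) {
    abort_idc(sprintf("state must have %d components", length(STATE_NAMES)), "bad_state")
  }
  bad <- !is.finite(state)
  if (any(bad)) {
    abort_idc(sprintf("non-finite state component: %s",
                      paste(STATE_NAMES[bad], collapse = ", ")), "bad_state")
  }
  scale <- pmax(abs(state), 1)
  neg <- state < -tol * scale - tol
  if (any(neg)) {
    abort_idc(sprintf("negative state component beyond tolerance: %s",
                      paste(STATE_NAMES[neg], collapse = ", ")), "bad_state")
  }
  invisible(state)
}

#' Reduced two-population derivatives (total bacteria, total yeast)
#'
#' The clump-free system of two cell ODEs used for stage-1 fitting against
#' mannose-supplemented (non-clumping) data: total bacteria `B` and total
#' yeast `Y` (transconjugants folded into `Y`), with the same growth,
#' secretion and consumption laws as the full model and no clump or
#' conjugation terms.
#'
#' @param state Named vector `c(B, Y, n_L, n_W, n_U, n_H, n_G)`.
#' @param sys An [idc_system()]; only the B and Y kinetics and genotypes are
#'   used.
#' @param t Time (h), unused (autonomous system).
#' @return Named derivative vector of the same shape.
#' @export
reduced_two_species_derivatives <- function(state, sys, t = 0) {
  stopifnot(inherits(sys, "idc_system"))
  if (any(!is.finite(state))) abort_idc("non-finite reduced state", "bad_state")
  p <- sys$params
  y <- pmax(state, 0)
  B <- y[1L]; Y <- y[2L]; n <- y[3:6]; n_G <- y[7L]
  aa <- c("L", "W", "U", "H")
  sec_Y_L <- if ("L" %in% sys$recipient$overproduces) p$sigma_L else
    if (sys$recipient$species == "yeast") p$sigma_L_basal else 0
  sec_B_W <- if ("W" %in% sys$donor$overproduces) p$sigma_W else 0

  fB <- n_G / (p$K$B["G"] + n_G)
  for (a in sys$req$B) fB <- fB * n[match(a, aa)] / (p$K$B[a] + n[match(a, aa)])
  fY <- n_G / (p$K$Y["G"] + n_G)
  for (a in sys$req$Y) fY <- fY * n[match(a, aa)] / (p$K$Y[a] + n[match(a, aa)])
  gB <- p$mu["B"] * fB
  gY <- p$mu["Y"] * fY

  dn <- c(sec_Y_L * Y, sec_B_W * B, 0, 0)
  for (a in sys$req$B) {
    i <- match(a, aa); dn[i] <- dn[i] - p$u$B[a] * gB * B
  }
  for (a in sys$req$Y) {
    i <- match(a, aa); dn[i] <- dn[i] - p$u$Y[a] * gY * Y
  }
  dn_G <- -(p$u$B["G"] * gB * B + p$u$Y["G"] * gY * Y)

  out <- c(gB * B - p$death["B"] * B, gY * Y - p$death["Y"] * Y, dn, dn_G)
  names(out) <- c("B", "Y", "n_L", "n_W", "n_U", "n_H", "n_G")
  out
}
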