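#' Kinetic and transfer parameters of the coculture model
#'
#' Units: cell counts are per 200 uL well; amino acids are well-average uM;
#' glucose is g/L; time is hours. Consumption coefficients `u` are the media
#' drawdown per new cell produced (uM per cell for amino acids, g/L per cell
#' for glucose).
#'
#' The two conjugative transfer terms are the fractional occurrence of
#' transfer per donor-recipient collision per hour: `gamma` for free
#' (planktonic) cells, `gamma_c` for cells inside bacteria-yeast clumps.
#' `P` is the proximity multiplier: clumped auxotrophic bacteria perceive, in
#' addition to the bulk concentration, a local standing concentration
#' `P * sigma * partners * tau_loc` of each amino acid their clump partners
#' secrete.
#'
#' Default kinetic values are order-of-magnitude reconstructions from cell
#' composition and typical minimal-media physiology (see the package
#' vignette); the defaults for `gamma` and `gamma_c` sit at the centers of
#' the fitted bands (2e-5 free, 3e-4 clumped).
#'
#' @param mu Named max growth rates (1/h) for `B` (donor bacteria), `Y`
#'   (recipient yeast), `T` (transconjugant yeast).
#' @param death Named first-order death rates (1/h).
#' @param K Named list of Monod half-saturation constants per population;
#'   each element is a vector with names `L, W, U, H` (uM) and `G` (g/L).
#' @param u Named list of per-new-cell consumption coefficients, same shape
#'   as `K`.
#' @param sigma_L Leucine secretion (uM/h per cell) by leucine-overproducing
#'   yeast.
#' @param sigma_W Tryptophan secretion (uM/h per cell) by
#'   tryptophan-overproducing bacteria.
#' @param sigma_L_basal Basal leucine release (uM/h per cell) by wild-type
#'   yeast; the mechanism behind this commensal benefit (secretion vs lysate)
#'   is unresolved, the model represents it as a small constant per-cell rate.
#' @param tau_loc Residence factor (h) converting partner secretion into a
#'   local standing concentration inside a clump.
#' @param k_a Clump association rate (1/(cell h)); forced to 0 when the media
#'   contain mannose.
#' @param k_d Clump dissociation rate (1/h).
#' @param gamma,gamma_c Free and clumped conjugative transfer terms (per
#'   collision per h).
#' @param P Proximity multiplier (dimensionless, >= 1 expected).
#' @param collision_norm `"per_total_cell"` (default; rate =
#'   `gamma * D * R / N_total`) or `"mass_action_density"` (Levin-style
#'   `gamma' * D * R / volume`, with `gamma` then carrying uL/cell/h units).
#' @param volume_uL Well volume (uL).
#' @return An object of class `idc_params` (a validated list).
#' @export
model_params <- function(mu = c(B = 0.50, Y = 0.35, T = 0.35),
                         death = c(B = 0.005, Y = 0.005, T = 0.005),
                         K = NULL,
                         u = NULL,
                         sigma_L = 5e-8,
                         sigma_W = 1e-9,
                         sigma_L_basal = 1e-9,
                         tau_loc = 1,
                         k_a = 2e-7,
                         k_d = 0.5,
                         gamma = 2e-5,
                         gamma_c = 3e-4,
                         P = 1,
                         collision_norm = c("per_total_cell", "mass_action_density"),
                         volume_uL = 200) {
  collision_norm <- match.arg(collision_norm)
  K_default <- list(
    B = c(L = 10, W = 10, U = 10, H = 10, G = 0.1),
    Y = c(L = 10, W = 10, U = 10, H = 10, G = 0.1),
    T = c(L = 10, W = 10, U = 10, H = 10, G = 0.1)
  )
  u_default <- list(
    B = c(L = 6e-7, W = 1e-7, U = 1e-7, H = 5e-8, G = 1e-8),
    Y = c(L = 3e-6, W = 1.7e-6, U = 1e-6, H = 5e-7, G = 2e-7),
    T = c(L = 3e-6, W = 1.7e-6, U = 1e-6, H = 5e-7, G = 2e-7)
  )
  K <- modify_pop_list(K_default, K)
  u <- modify_pop_list(u_default, u)

  p <- list(mu = complete_pop(mu, c(B = 0.50, Y = 0.35, T = 0.35)),
            death = complete_pop(death, c(B = 0.005, Y = 0.005, T = 0.005)),
            K = K, u = u,
            sigma_L = sigma_L, sigma_W = sigma_W, sigma_L_basal = sigma_L_basal,
            tau_loc = tau_loc, k_a = k_a, k_d = k_d,
            gamma = gamma, gamma_c = gamma_c, P = P,
            collision_norm = collision_norm, volume_uL = volume_uL)

  scalars <- c("sigma_L", "sigma_W", "sigma_L_basal", "tau_loc", "k_a", "k_d",
               "gamma", "gamma_c", "P", "volume_uL")
  for (nm in scalars) {
    if (!is_scalar_number(p[[nm]]) || p[[nm]] < 0) {
      abort_idc(sprintf("parameter %s must be a non-negative number", nm), "bad_params")
    }
  }
  if (any(p$mu < 0) || any(p$death < 0)) {
    abort_idc("growth and death rates must be >= 0", "bad_params")
  }
  for (pop in c("B", "Y", "T")) {
    if (any(p$K[[pop]] <= 0)) {
      abort_idc(sprintf("Monod constants for %s must be > 0", pop), "bad_params")
    }
    if (any(p$u[[pop]] < 0)) {
      abort_idc(sprintf("consumption coefficients for %s must be >= 0", pop), "bad_params")
    }
  }
  structure(p, class = "idc_params")
}

complete_pop <- function(x, default) {
  out <- default
  out[names(x)] <- x
  out[c("B", "Y", "T")]
}

modify_pop_list <- function(default, override) {
  if (is.null(override)) return(default)
  for (pop in names(override)) {
    if (!pop %in% c("B", "Y", "T")) {
      abort_idc(sprintf("unknown population '%s' in parameter list", pop), "bad_params")
    }
    v <- default[[pop]]
    v[names(override[[pop]])] <- override[[pop]]
    default[[pop]] <- v
  }
  default
}

#' Bundle parameters, genotypes and media into a simulatable system
#'
#' @param params [model_params()] object.
#' @param donor,recipient [strain_genotype()] objects; the donor must be a
#'   bacterium with `donor_mode != "none"` for conjugation to occur, the
#'   recipient a yeast.
#' @param media [media_config()] object.
#' @return An object of class `idc_system`.
#' @export
idc_system <- function(params = model_params(),
                       donor = genotype_preset("E_cross"),
                       recipient = genotype_preset("S_cross"),
                       media = media_config(f_L = 0.15, f_W = 0.15)) {
  stopifnot(inherits(params, "idc_params"),
            inherits(donor, "idc_genotype"),
            inherits(recipient, "idc_genotype"),
            inherits(media, "idc_media"))
  if (donor$species != "bacterium") {
    abort_idc("the donor population must be a bacterium", "bad_genotype")
  }
  if (recipient$species != "yeast") {
    abort_idc("the recipient population must be a yeast", "bad_genotype")
  }
  structure(
    list(params = params, donor = donor, recipient = recipient, media = media,
         req = list(B = donor$auxotrophies,
                    Y = recipient$auxotrophies,
                    T = transconjugant_requirements(recipient, donor))),
    class = "idc_system"
  )
}

#' Initial well state
#'
#' State components: free/clumped donors (`B_f`, `B_c`), recipients
#' (`Y_f`, `Y_c`), transconjugants (`T_f`, `T_c`), nutrients `n_L, n_W, n_U,
#' n_H` (uM), glucose `n_G` (g/L), and the bookkeeping integral `T_cum` of
#' all conjugation events since time zero (not subject to dilution).
#'
#' @param media [media_config()] supplying the initial nutrient levels.
#' @param B,Y,T Initial free cells per well (defaults: 1e7 donors and
#'   recipients, no transconjugants).
#' @return Named numeric state vector.
#' @export
coculture_state <- function(media, B = 1e7, Y = 1e7, T = 0) {
  stopifnot(inherits(media, "idc_media"))
  if (any(c(B, Y, T) < 0)) abort_idc("initial cell counts must be >= 0", "bad_state")
  c(B_f = B, B_c = 0, Y_f = Y, Y_c = 0, T_f = T, T_c = 0,
    n_L = unname(concentration(media, "L")),
    n_W = unname(concentration(media, "W")),
    n_U = unname(concentration(media, "U")),
    n_H = unname(concentration(media, "H")),
    n_G = media$glucose_gL,
    T_cum = 0)
}

STATE_NAMES <- c("B_f", "B_c", "Y_f", "Y_c", "T_f", "T_c",
                 "n_L", "n_W", "n_U", "n_H", "n_G", "T_cum")
CELL_NAMES <- c("B_f", "B_c", "Y_f", "Y_c", "T_f", "T_c")
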