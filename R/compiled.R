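# Parameter packing for the compiled right-hand sides (see src/idc_rhs.c for
# the block layouts). Mirrors compile_rhs(); a test asserts agreement.

pack_full_parms <- function(sys) {
  p <- sys$params
  sec_Y_L <- if ("L" %in% sys$recipient$overproduces) p$sigma_L else
    if (sys$recipient$species == "yeast") p$sigma_L_basal else 0
  sec_B_W <- if ("W" %in% sys$donor$overproduces) p$sigma_W else 0
  donor_active <- sys$donor$donor_mode != "none" &&
    sys$donor$payload != "crispr_no_oriT"
  aa <- c("L", "W", "U", "H")
  mask <- function(req) as.numeric(aa %in% req)
  c(p$mu, p$death,
    p$K$B, p$K$Y, p$K$T,
    p$u$B, p$u$Y, p$u$T,
    sec_Y_L, sec_B_W, p$tau_loc,
    if (sys$media$mannose) 0 else p$k_a, p$k_d,
    if (donor_active) p$gamma else 0,
    if (donor_active) p$gamma_c else 0,
    p$P,
    as.numeric(p$collision_norm == "per_total_cell"), p$volume_uL,
    as.numeric("L" %in% sys$req$B && sec_Y_L > 0),
    mask(sys$req$B), mask(sys$req$Y), mask(sys$req$T))
}

pack_reduced_parms <- function(sys) {
  p <- sys$params
  sec_Y_L <- if ("L" %in% sys$recipient$overproduces) p$sigma_L else
    if (sys$recipient$species == "yeast") p$sigma_L_basal else 0
  sec_B_W <- if ("W" %in% sys$donor$overproduces) p$sigma_W else 0
  aa <- c("L", "W", "U", "H")
  mask <- function(req) as.numeric(aa %in% req)
  c(p$mu["B"], p$mu["Y"], p$death["B"], p$death["Y"],
    p$K$B, p$K$Y, p$u$B, p$u$Y,
    sec_Y_L, sec_B_W, mask(sys$req$B), mask(sys$req$Y))
}
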