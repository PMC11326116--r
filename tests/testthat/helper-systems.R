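# small systems and fixtures shared across tests

crossfeeder_system <- function(f_LW = 0.15, mannose = FALSE, ...) {
  idc_system(params = model_params(...),
             donor = genotype_preset("E_cross"),
             recipient = genotype_preset("S_cross"),
             media = media_config(f_L = f_LW, f_W = f_LW, mannose = mannose))
}

# a parameter set with all dynamics switched off
inert_params <- function() {
  model_params(mu = c(B = 0, Y = 0, T = 0), death = c(B = 0, Y = 0, T = 0),
               sigma_L = 0, sigma_W = 0, sigma_L_basal = 0,
               k_a = 0, k_d = 0, gamma = 0, gamma_c = 0)
}

random_state <- function(seed) {
  set.seed(seed)
  c(B_f = runif(1, 0, 1e8), B_c = runif(1, 0, 1e8),
    Y_f = runif(1, 0, 1e7), Y_c = runif(1, 0, 1e7),
    T_f = runif(1, 0, 1e5), T_c = runif(1, 0, 1e5),
    n_L = runif(1, 0, 800), n_W = runif(1, 0, 250),
    n_U = runif(1, 0, 180), n_H = runif(1, 0, 95),
    n_G = runif(1, 0, 20), T_cum = 0)
}
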