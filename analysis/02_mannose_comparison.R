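#!/usr/bin/env Rscript
# Effect of mannose (clump disruption) on interdomain conjugation: identical
# 6-day crossfeeder runs with and without mannose at the fitted-band transfer
# terms (gamma = 2e-5 free, gamma_c = 3e-4 clumped).

suppressPackageStartupMessages(library(idcsim))
dir.create("results", showWarnings = FALSE)

protocol <- batch_protocol(n_days = 6)
run_arm <- function(mannose) {
  media <- media_config(f_L = 0.15, f_W = 0.15, mannose = mannose)
  sys <- idc_system(model_params(gamma = 2e-5, gamma_c = 3e-4),
                    genotype_preset("E_cross"), genotype_preset("S_cross"),
                    media)
  run_batch_protocol(coculture_state(media), sys, protocol)
}
no_man <- run_arm(FALSE)
man <- run_arm(TRUE)

cmp <- data.frame(day = no_man$daily$day,
                  T_cum_no_mannose = no_man$daily$T_cum,
                  T_cum_mannose = man$daily$T_cum,
                  fold = no_man$daily$T_cum / man$daily$T_cum)
write.csv(cmp, "results/mannose_comparison.csv", row.names = FALSE)
print(format(cmp, digits = 4), row.names = FALSE)
cat(sprintf("\nDisrupting clumps with mannose suppresses cumulative day-6 IDC %.1f-fold:\nconjugation in this regime is carried almost entirely by clumped cells.\n",
            cmp$fold[6]))
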