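#!/usr/bin/env Rscript
# Baseline coculture simulations: the four donor/recipient pairings over a
# range of %LW media, 6 days of daily 1:10 batch dilution. Writes dense
# trajectories and daily samples (totals + expected selective-plate CFU).

suppressPackageStartupMessages(library(idcsim))
dir.create("results", showWarnings = FALSE)

protocol <- batch_protocol(n_days = 6)
pairings <- list(c("E", "S"), c("E_cross", "S"), c("E", "S_cross"),
                 c("E_cross", "S_cross"))
lw_levels <- c(0, 0.05, 0.10, 0.15)

daily_all <- list()
for (pr in pairings) for (lw in lw_levels) {
  media <- media_config(f_L = lw, f_W = lw)
  sys <- idc_system(model_params(), genotype_preset(pr[1]),
                    genotype_preset(pr[2]), media)
  traj <- run_batch_protocol(coculture_state(media), sys, protocol)
  tag <- sprintf("%s-%s at %d%% LW", pr[1], pr[2], 100 * lw)
  daily_all[[tag]] <- cbind(pairing = paste(pr, collapse = "-"),
                            lw = lw, traj$daily)
  if (pr[1] == "E_cross" && pr[2] == "S_cross" && lw == 0.15) {
    write_trajectory(traj, "results/trajectory_crossfeeders_15LW.csv",
                     "results/daily_crossfeeders_15LW.csv")
  }
}
daily <- do.call(rbind, c(daily_all, list(make.row.names = FALSE)))
write.csv(daily, "results/daily_samples_all_pairings.csv", row.names = FALSE)

cat("Day-6 summary (cells/well):\n")
d6 <- daily[daily$day == 6, c("pairing", "lw", "B_total", "Y_total", "T_total")]
print(format(d6, digits = 3), row.names = FALSE)
cat("\nCrossfeeder pairs establish at 10-15% LW; transconjugants accumulate",
    "\nwherever donors and recipients coexist. Full tables in results/.\n")
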