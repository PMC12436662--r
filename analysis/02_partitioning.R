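#!/usr/bin/env Rscript
# Condensate partitioning: segment the simulated condensate fields, compute
# per-condensate partition coefficients and transfer free energies, and
# check the planted values are recovered.

suppressMessages(library(condactin))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (kp in c(2, 4, 10)) {
  sc <- make_condensate_field(n = 6, kp_true = kp, noise_sd = 2,
                              seed = 100 + kp)
  seg <- segment_condensates(sc$image, gaussian_sigma_px = 2,
                             min_area_px = 20)
  pk <- partition_coefficient(sc$image, seg, temperature_K = 298.15)
  keep <- remove_outliers_rout(pk$Kp, Q = 1)
  rows[[length(rows) + 1L]] <-
    data.frame(kp_planted = kp, region_id = pk$region_id, Kp = pk$Kp,
               deltaG_kcal_mol = pk$deltaG_kcal_mol,
               outlier = !pk$Kp %in% keep$kept)
  cat(sprintf("planted Kp = %2g: %d condensates, mean measured Kp = %.3f, mean dG = %+.4f kcal/mol\n",
              kp, nrow(pk), mean(keep$kept),
              mean(delta_g(keep$kept))))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/partitioning.csv", row.names = FALSE)
cat("wrote results/partitioning.csv\n")
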