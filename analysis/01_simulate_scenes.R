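#!/usr/bin/env Rscript
# Generate the ground-truthed synthetic scenes used by the downstream
# analysis scripts and write them (image + truth sidecars) under
# results/scenes/. Every scene is fully determined by its seed.

suppressMessages(library(condactin))

out <- "results/scenes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# condensate fields at three planted partition coefficients
for (kp in c(2, 4, 10)) {
  sc <- make_condensate_field(n = 6, kp_true = kp, noise_sd = 2,
                              seed = 100 + kp)
  write_scene(sc, file.path(out, sprintf("condensates_kp%g", kp)))
}

# an actin aster and a two-condensate bridged scene
write_scene(make_aster_scene(1, 6, 40, seed = 11),
            file.path(out, "aster"))
write_scene(make_aster_scene(2, 4, 30, seed = 12, dim = c(160L, 160L),
                             bridge = TRUE),
            file.path(out, "aster_bridged"))

# enrichment movie with drift (reference kinetics parameters)
write_scene(make_enrichment_movie(n_frames = 36,
                                  drift_px_per_frame = c(0.5, 0),
                                  noise_sd = 0.01, seed = 13,
                                  dim = c(96L, 64L)),
            file.path(out, "enrichment_movie"), axes = "TYX")

# two-channel bouton scene and a cluster-density scene
write_scene(make_bouton_scene(15, 0.5, seed = 14, noise_sd = 0.01),
            file.path(out, "boutons"))
write_scene(make_cluster_scene(4, 2, 2, seed = 15),
            file.path(out, "clusters"))

# axial ring profile (0.19 um period at 20 nm pixels)
rp <- make_ring_profile(0.19, 0.02, 10, noise_sd = 0.1, seed = 16)
write.csv(data.frame(position_um = rp$position_um,
                     intensity = rp$profile),
          file.path(out, "ring_profile.csv"), row.names = FALSE)

cat("wrote synthetic scenes to", out, "\n")
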