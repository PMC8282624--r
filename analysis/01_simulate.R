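#!/usr/bin/env Rscript
# Stage 1 — simulate the study system.
#
# Builds the demo landscape (60 x 60 geographic grid with a north-south
# cordillera, a wet south / dry north precipitation gradient and smooth
# soil fields) and samples occurrence records for eight virtual tree
# species: four with wet-forest niches, four with dry-forest niches.
# Ground-truth niches are known, so every later stage can be checked.

library(pftshift)

dir.create("results/state", recursive = TRUE, showWarnings = FALSE)
cfg <- demo_config(out_dir = "results/demo", seed = 1)

grid <- do.call(grid_spec, cfg$grid)
env <- generate_landscape(grid, cfg$landscape, seed = 101)
write_env_stack(env, "results/env")

occ <- do.call(rbind, lapply(seq_along(cfg$species), function(i) {
  s <- names(cfg$species)[i]
  sp <- cfg$species[[s]]
  sample_occurrences(env, niche_spec(s, unlist(sp$optima), unlist(sp$breadths),
                                     sp$prob_max),
                     n = sp$n_records, seed = 200 + i)
}))
class(occ) <- c("occurrence_set", "data.frame")
write_occurrences(occ, "results/occurrences.csv")

saveRDS(list(cfg = cfg, grid = grid, env = env, occ = occ),
        "results/state/01_simulate.rds")

cat("Landscape:", grid$n_rows, "x", grid$n_cols, "cells; elevation",
    paste(round(range(env$layers$elevation)), collapse = "-"), "m\n")
cat("Sampled", nrow(occ), "occurrence records for",
    length(unique(occ$species)), "species\n")
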