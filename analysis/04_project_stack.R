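#!/usr/bin/env Rscript
# Stage 4 — scenario projection and PFT stacking.
#
# Applies the drying/warming delta, clamps scenario layers to the training
# range, projects a 4-per-learner replicate subset onto present and
# scenario climates, ensembles the maps per species, binarizes with
# per-learner maxSSS thresholds under 3-of-4 algorithm agreement, and
# stacks the four member species per PFT into richness, bS-SDM and
# presence maps.

library(pftshift)

st1 <- readRDS("results/state/01_simulate.rds")
st2 <- readRDS("results/state/02_prepare.rds")
st3 <- readRDS("results/state/03_fit.rds")
cfg <- st1$cfg
env <- st1$env

envs <- list(present = env)
for (lab in names(cfg$scenarios)) {
  sc <- cfg$scenarios[[lab]]
  delta <- climate_delta(lab, offset = sc$offset, factor = sc$factor)
  cl <- clamp_to_range(apply_climate_delta(env, delta), st2$ranges)
  cat(sprintf("scenario %s: novel-climate fraction %.3f (temperature)\n",
              lab, cl$novel_fraction[["temperature"]]))
  envs[[lab]] <- cl$env
}

ensembles <- list()
selected <- list()
for (i in seq_along(st3$fits)) {
  s <- names(st3$fits)[i]
  keep <- st3$retained[[s]]
  sel <- select_projection_replicates(
    unlist(st3$fits[[s]][keep], recursive = FALSE, use.names = FALSE),
    k = cfg$sdm$k_project, seed = 600 + i)
  selected[[s]] <- sel
  ensembles[[s]] <- lapply(envs, function(e)
    species_ensemble(sel, e, retained = keep))
}

pfts <- list()
for (lab in names(envs)) {
  pfts[[lab]] <- lapply(names(cfg$pfts), function(p)
    pft_result(p, lapply(ensembles[unlist(cfg$pfts[[p]])], `[[`, lab),
               min_agree = cfg$thresholds$min_agree,
               presence_min = cfg$thresholds$presence_min))
  names(pfts[[lab]]) <- names(cfg$pfts)
  for (p in names(cfg$pfts))
    write_ascii_grid(pfts[[lab]][[p]]$richness, st1$grid,
                     sprintf("results/%s_%s_richness.asc", p, lab))
}

saveRDS(list(envs = envs, ensembles = ensembles, selected = selected,
             pfts = pfts), "results/state/04_project.rds")

for (lab in names(pfts))
  for (p in names(pfts[[lab]]))
    cat(sprintf("%-8s %-9s mean richness %.2f, presence cells %d\n",
                lab, p, mean(pfts[[lab]][[p]]$richness, na.rm = TRUE),
                sum(pfts[[lab]][[p]]$presence)))
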