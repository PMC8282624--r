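#!/usr/bin/env Rscript
# Stage 2 — occurrence thinning and predictor screening.
#
# Thins records to one per species per grid cell, checks the per-species
# minimum-record rule, and screens the predictors for multicollinearity by
# stepwise VIF elimination on a pooled presence + background sample.

library(pftshift)

st <- readRDS("results/state/01_simulate.rds")
env <- st$env

occ_thin <- thin_to_grid(st$occ, st$grid)
write_occurrences(occ_thin, "results/occurrences_thinned.csv")
rec <- check_min_records(occ_thin, minimum = st$cfg$thresholds$min_records)
print(rec)
stopifnot(all(rec$pass))

candidates <- setdiff(names(env$layers), "elevation")
idx <- cell_index(st$grid, occ_thin$lon, occ_thin$lat)
xp <- env_values(env, idx$row, idx$col, candidates)
set.seed(301)
bg_cells <- sample(which(!is.na(env$layers[[1]])), 2000)
xb <- env_values(env, ((bg_cells - 1) %% st$grid$n_rows) + 1,
                 ((bg_cells - 1) %/% st$grid$n_rows) + 1, candidates)
screen <- vif_stepwise(rbind(xp, xb), threshold = st$cfg$thresholds$vif)
print(screen)
write.csv(screen$steps, "results/vif_screen.csv", row.names = FALSE)

saveRDS(list(occ = occ_thin, vars = screen$retained,
             ranges = training_ranges(env)),
        "results/state/02_prepare.rds")

cat("Thinned", nrow(st$occ), "->", nrow(occ_thin), "records;",
    length(screen$retained), "of", length(candidates),
    "predictors retained after VIF screening\n")
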