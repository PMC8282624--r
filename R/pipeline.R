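# Deterministic per-stage seed derivation from the run seed (kept < 2^31).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483629L) + 1L
}

default_thresholds <- function() {
  list(vif = 10, filter = 0.7, min_agree = 3, presence_min = 2,
       quantile = 0.05, min_records = 200)
}

#' Validate a run configuration
#'
#' A run configuration describes one full analysis: the grid and landscape
#' generator (or input files), the virtual species and their PFT
#' membership, the learner roster, the scenario deltas, the seeds and the
#' fixed thresholds (VIF 10, metric filter 0.7, agreement 3, bS-SDM
#' presence 2, lower-boundary quantile 0.05).
#'
#' @param config named list, or path to a YAML file with the same
#'   structure (see `inst/extdata/demo_config.yaml`).
#' @return validated config of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  req <- c("grid", "species", "pfts", "learners", "scenarios", "seed")
  missing_f <- setdiff(req, names(config))
  if (length(missing_f))
    stop("config lacks field(s): ", paste(missing_f, collapse = ", "))
  config$thresholds <- utils::modifyList(default_thresholds(),
                                         config$thresholds %||% list())
  config$sdm <- utils::modifyList(
    list(n_replicates = 100, k_project = 10, train_frac = 0.7,
         pa_n_background = 10000),
    config$sdm %||% list())
  config$uncertainty <- utils::modifyList(list(n_cells = 150),
                                          config$uncertainty %||% list())
  known <- names(default_learners())
  bad <- setdiff(unlist(config$learners), known)
  if (length(bad))
    stop("unknown learner name(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(known, collapse = ", "), ")")
  if (anyDuplicated(names(config$scenarios)))
    stop("scenario labels must be unique")
  undef <- setdiff(unlist(config$pfts), names(config$species))
  if (length(undef))
    stop("PFT member species without a niche definition: ",
         paste(undef, collapse = ", "))
  for (s in names(config$species)) {
    sp <- config$species[[s]]
    if (is.null(sp$optima) || is.null(sp$breadths))
      stop("species '", s, "' needs optima and breadths")
  }
  class(config) <- c("run_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full stacked-SDM analysis from one configuration
#'
#' Composes every stage in order: landscape simulation, occurrence
#' sampling and thinning, VIF predictor screening, per-species ensemble
#' fitting, metric-based learner filtering, scenario projection with
#' clamping, PFT stacking, dominance and transition-flow mapping,
#' latitude-altitude shift statistics, fragmentation classification, and
#' ANOVA uncertainty partitioning. All stage outputs are written under
#' `config$out_dir` with deterministic names, and a JSON manifest records
#' seeds, thresholds, per-stage wall times and output digests.
#'
#' @param config a [run_config()] (or list/YAML path coercible to one).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with `manifest` and the in-memory `results`
#'   of each stage.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- run_config(config)
  out_dir <- config$out_dir %||% "pipeline_output"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  th <- config$thresholds
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = seed, thresholds = th, stages = list())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    say("stage %-12s done (%.1fs)", name, manifest$stages[[name]]$elapsed_s)
    val
  }

  ## -- simulate ------------------------------------------------------------
  results$env <- t_stage("simulate", {
    g <- do.call(grid_spec, config$grid)
    env <- generate_landscape(g, config$landscape %||% list(),
                              seed = derive_seed(seed, 1))
    write_env_stack(env, file.path(out_dir, "env"))
    occ_all <- list()
    for (i in seq_along(config$species)) {
      s <- names(config$species)[i]
      sp <- config$species[[s]]
      niche <- niche_spec(s, unlist(sp$optima), unlist(sp$breadths),
                          prob_max = sp$prob_max %||% 1)
      occ_all[[s]] <- sample_occurrences(env, niche,
                                         n = sp$n_records %||% 500,
                                         seed = derive_seed(seed, 10 + i))
    }
    occ <- do.call(rbind, occ_all)
    class(occ) <- c("occurrence_set", "data.frame")
    write_occurrences(occ, file.path(out_dir, "occurrences.csv"))
    results$occ <- occ
    env
  })
  env <- results$env

  ## -- prep ----------------------------------------------------------------
  results$prep <- t_stage("prep", {
    occ_thin <- thin_to_grid(results$occ, env$grid)
    write_occurrences(occ_thin, file.path(out_dir, "occurrences_thinned.csv"))
    rec <- check_min_records(occ_thin, minimum = th$min_records,
                             species = names(config$species))
    if (any(!rec$pass) && !isTRUE(config$allow_few_records))
      stop("species below the minimum record count: ",
           paste(rec$species[!rec$pass], collapse = ", "))
    # pooled presence + background sample for collinearity screening
    candidates <- setdiff(names(env$layers), "elevation")
    idx <- cell_index(env$grid, occ_thin$lon, occ_thin$lat)
    xp <- env_values(env, idx$row, idx$col, candidates)
    bg <- with_seed(derive_seed(seed, 2), {
      usable <- which(!is.na(env$layers[[1L]]))
      sample(usable, min(5000L, length(usable)))
    })
    xb <- env_values(env, ((bg - 1L) %% env$grid$n_rows) + 1L,
                     ((bg - 1L) %/% env$grid$n_rows) + 1L, candidates)
    screen <- vif_stepwise(rbind(xp, xb), threshold = th$vif)
    utils::write.csv(screen$steps, file.path(out_dir, "vif_screen.csv"),
                     row.names = FALSE)
    list(occ = occ_thin, records = rec, screen = screen,
         vars = screen$retained, ranges = training_ranges(env))
  })
  vars <- results$prep$vars

  ## -- fit -----------------------------------------------------------------
  results$fits <- t_stage("fit", {
    learners <- default_learners(config$sdm$pa_n_background)[unlist(config$learners)]
    fits <- list()
    for (i in seq_along(config$species)) {
      s <- names(config$species)[i]
      occ_s <- results$prep$occ[results$prep$occ$species == s, , drop = FALSE]
      fits[[s]] <- list()
      for (j in seq_along(learners)) {
        lr <- learners[[j]]
        pa <- draw_pseudo_absences(env, occ_s, lr,
                                   seed = derive_seed(seed, 1000 + 50 * i + j))
        fits[[s]][[lr$name]] <- fit_replicates(
          lr, occ_s, pa, env,
          n_replicates = config$sdm$n_replicates,
          train_frac = config$sdm$train_frac,
          seed = derive_seed(seed, 2000 + 50 * i + j),
          vars = vars, species = s)
      }
    }
    metrics <- do.call(rbind, lapply(fits, function(fl)
      replicate_metrics(unlist(fl, recursive = FALSE, use.names = FALSE))))
    utils::write.csv(metrics, file.path(out_dir, "replicate_metrics.csv"),
                     row.names = FALSE)
    fits
  })

  ## -- evaluate ------------------------------------------------------------
  results$retained <- t_stage("evaluate", {
    presence_only <- names(Filter(function(l) l$presence_only,
                                  default_learners()))
    retained <- lapply(names(results$fits), function(s) {
      m <- learner_mean_metrics(unlist(results$fits[[s]], recursive = FALSE,
                                       use.names = FALSE))
      filter_models(m, threshold = th$filter, presence_only = presence_only)
    })
    names(retained) <- names(results$fits)
    utils::write.csv(
      data.frame(species = rep(names(retained), lengths(retained)),
                 learner = unlist(retained)),
      file.path(out_dir, "retained_learners.csv"), row.names = FALSE)
    retained
  })

  ## -- project -------------------------------------------------------------
  results$scenario_envs <- t_stage("project", {
    envs <- list(present = env)
    for (lab in names(config$scenarios)) {
      sc <- config$scenarios[[lab]]
      delta <- climate_delta(lab, offset = sc$offset %||% list(),
                             factor = sc$factor %||% list())
      clamped <- clamp_to_range(apply_climate_delta(env, delta),
                                results$prep$ranges)
      for (nm in names(clamped$novelty))
        if (clamped$novel_fraction[[nm]] > 0)
          write_ascii_grid(clamped$novelty[[nm]] * 1, env$grid,
                           file.path(out_dir,
                                     sprintf("novelty_%s_%s.asc", lab, nm)))
      envs[[lab]] <- clamped$env
    }
    envs
  })

  results$ensembles <- t_stage("ensemble", {
    ens <- list()
    for (i in seq_along(results$fits)) {
      s <- names(results$fits)[i]
      keep <- results$retained[[s]]
      fits_s <- unlist(results$fits[[s]][keep], recursive = FALSE,
                       use.names = FALSE)
      sel <- select_projection_replicates(
        fits_s, k = min(config$sdm$k_project, config$sdm$n_replicates),
        seed = derive_seed(seed, 3000 + i))
      ens[[s]] <- lapply(results$scenario_envs, function(e)
        species_ensemble(sel, e, retained = keep))
      results$selected_fits[[s]] <- sel
    }
    ens
  })

  ## -- stack ---------------------------------------------------------------
  results$pft_results <- t_stage("stack", {
    out <- list()
    for (lab in names(results$scenario_envs)) {
      out[[lab]] <- lapply(names(config$pfts), function(p) {
        members <- unlist(config$pfts[[p]])
        pr <- pft_result(p, lapply(results$ensembles[members], `[[`, lab),
                         min_agree = th$min_agree,
                         presence_min = th$presence_min)
        write_ascii_grid(pr$richness, env$grid,
                         file.path(out_dir, sprintf("%s_%s_richness.asc", p, lab)))
        write_ascii_grid(pr$bs_sdm, env$grid,
                         file.path(out_dir, sprintf("%s_%s_bssdm.asc", p, lab)))
        pr
      })
      names(out[[lab]]) <- names(config$pfts)
    }
    out
  })

  ## -- dominance -----------------------------------------------------------
  results$dominance <- t_stage("dominance", {
    areas <- cell_area_km2(env$grid)
    doms <- lapply(results$pft_results, dominant_pft,
                   order = names(config$pfts))
    for (lab in names(doms)) {
      codes <- matrix(match(doms[[lab]]$labels, doms[[lab]]$classes),
                      env$grid$n_rows, env$grid$n_cols)
      write_ascii_grid(codes, env$grid,
                       file.path(out_dir, sprintf("dominance_%s.asc", lab)))
    }
    jsonlite::write_json(list(classes = doms[[1L]]$classes),
                         file.path(out_dir, "dominance_classes.json"))
    af <- do.call(rbind, lapply(names(doms), function(lab)
      cbind(scenario = lab, area_fractions(doms[[lab]], areas))))
    utils::write.csv(af, file.path(out_dir, "area_fractions.csv"),
                     row.names = FALSE)
    flows <- lapply(names(doms)[-1L], function(lab)
      transition_flows(doms$present, doms[[lab]], areas))
    names(flows) <- names(doms)[-1L]
    for (lab in names(flows))
      jsonlite::write_json(
        list(classes = rownames(flows[[lab]]),
             flow_km2 = unname(apply(flows[[lab]], 1L, as.numeric,
                                     simplify = FALSE))),
        file.path(out_dir, sprintf("flows_%s.json", lab)))
    list(maps = doms, area_fractions = af, flows = flows)
  })

  ## -- shifts --------------------------------------------------------------
  results$shifts <- t_stage("shifts", {
    elev <- env$layers$elevation
    rows <- list()
    for (p in names(config$pfts)) {
      pts0 <- presence_lat_alt(results$pft_results$present[[p]]$presence,
                               elev, env$grid)
      for (lab in names(results$pft_results)) {
        pts <- presence_lat_alt(results$pft_results[[lab]][[p]]$presence,
                                elev, env$grid)
        if (nrow(pts) == 0L || nrow(pts0) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            pft = p, scenario = lab, n_cells = nrow(pts),
            lower_boundary_m = NA_real_, shift_m = NA_real_,
            n_modes = NA_integer_, mode_locations = "")
          next
        }
        modes <- latitudinal_modes(pts)
        rows[[length(rows) + 1L]] <- data.frame(
          pft = p, scenario = lab, n_cells = nrow(pts),
          lower_boundary_m = lower_boundary(pts, th$quantile),
          shift_m = boundary_shift(pts0, pts, th$quantile),
          n_modes = modes$n_modes,
          mode_locations = paste(round(modes$locations, 3), collapse = ";"))
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "shifts.csv"), row.names = FALSE)
    tab
  })

  ## -- fragmentation -------------------------------------------------------
  results$fragmentation <- t_stage("fragmentation", {
    doms <- results$dominance$maps
    areas <- cell_area_km2(env$grid)
    tabs <- list()
    for (p in names(config$pfts)) {
      base_bin <- (doms$present$labels == p) * 1L
      for (lab in names(doms)) {
        bin <- (doms[[lab]]$labels == p) * 1L
        pp <- pf_pff(bin)
        frag <- classify_fragmentation(pp$pf, pp$pff, bin,
                                       presence_baseline = base_bin,
                                       pft = p, scenario = lab)
        write_ascii_grid(frag$classes, env$grid,
                         file.path(out_dir,
                                   sprintf("fragmentation_%s_%s.asc", p, lab)))
        tabs[[length(tabs) + 1L]] <-
          cbind(pft = p, scenario = lab, fragmentation_summary(frag, areas))
      }
    }
    tab <- do.call(rbind, tabs)
    utils::write.csv(tab, file.path(out_dir, "fragmentation_summary.csv"),
                     row.names = FALSE)
    tab
  })

  ## -- uncertainty ---------------------------------------------------------
  results$uncertainty <- t_stage("uncertainty", {
    g <- env$grid
    usable <- which(!is.na(env$layers[[1L]]))
    cells <- with_seed(derive_seed(seed, 4),
                       sample(usable, min(config$uncertainty$n_cells,
                                          length(usable))))
    crow <- ((cells - 1L) %% g$n_rows) + 1L
    ccol <- ((cells - 1L) %/% g$n_rows) + 1L
    scen_meta <- lapply(names(config$scenarios), function(lab)
      list(rcp = config$scenarios[[lab]]$rcp %||% lab,
           gcm = config$scenarios[[lab]]$gcm %||% "GCM-1"))
    names(scen_meta) <- names(config$scenarios)
    partitions <- list()
    for (s in names(results$selected_fits)) {
      long <- list()
      for (f in results$selected_fits[[s]]) {
        for (lab in names(config$scenarios)) {
          e <- results$scenario_envs[[lab]]
          x <- env_values(e, crow, ccol, f$vars)
          long[[length(long) + 1L]] <- data.frame(
            cell = seq_along(cells), algorithm = f$learner,
            replicate = f$replicate,
            rcp = scen_meta[[lab]]$rcp, gcm = scen_meta[[lab]]$gcm,
            value = f$model(x))
        }
      }
      long <- do.call(rbind, long)
      partitions[[s]] <- lapply(split(long, long$cell), anova_partition)
    }
    ranking <- rank_factors(unlist(partitions, recursive = FALSE,
                                   use.names = FALSE))
    utils::write.csv(ranking, file.path(out_dir, "uncertainty_ranking.csv"),
                     row.names = FALSE)
    list(partitions = partitions, ranking = ranking)
  })

  ## -- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest$outputs <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(file.path(out_dir, f))))
  manifest$n_species <- length(config$species)
  manifest$learners <- unlist(config$learners)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}

#' Demo configuration
#'
#' A small two-PFT (wet-like and dry-like forest, four virtual species
#' each) configuration on a 60 x 60 grid with one drying-and-warming
#' scenario, sized so the full pipeline runs in minutes on one CPU.
#'
#' @param out_dir output directory for pipeline results.
#' @param seed run seed.
#' @return a [run_config()].
#' @export
demo_config <- function(out_dir = tempfile("pftshift_demo_"), seed = 1L) {
  cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                     package = "pftshift"))
  cfg$out_dir <- out_dir
  cfg$seed <- seed
  run_config(cfg)
}
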