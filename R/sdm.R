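#' Draw pseudo-absence points for one species
#'
#' Strategies:
#' * `random` — uniform over non-presence, non-masked cells;
#' * `disk` — uniform over cells whose distance (in cell units) to the
#'   nearest presence cell lies within the learner's annulus radii;
#' * `stratified` — uniform over cells in environmental bins (quantile bins
#'   of the climate layers) that contain no presence.
#'
#' No point ever falls on a presence cell. Points are placed at cell
#' centers.
#'
#' @param env an [env_stack()].
#' @param occ an [occurrence_set()] for one species (thinned).
#' @param spec a [learner_spec()] (provides strategy, count rule, radii).
#' @param seed integer seed.
#' @param n_bins quantile bins per climate layer for the stratified
#'   strategy.
#' @return data.frame with columns `row`, `col`, `lon`, `lat`.
#' @export
draw_pseudo_absences <- function(env, occ, spec, seed = 1L, n_bins = 5) {
  g <- env$grid
  idx <- cell_index(g, occ$lon, occ$lat)
  pres_cells <- unique((idx$col - 1L) * g$n_rows + idx$row)
  usable <- which(!is.na(env$layers[[1L]]))
  candidates <- setdiff(usable, pres_cells)
  if (spec$pa_strategy == "disk") {
    pr <- ((pres_cells - 1L) %% g$n_rows) + 1L
    pc <- ((pres_cells - 1L) %/% g$n_rows) + 1L
    cr <- ((candidates - 1L) %% g$n_rows) + 1L
    cc <- ((candidates - 1L) %/% g$n_rows) + 1L
    dmin <- rep(Inf, length(candidates))
    for (j in seq_along(pr)) {
      d <- sqrt((cr - pr[j])^2 + (cc - pc[j])^2)
      dmin <- pmin(dmin, d)
    }
    keep <- dmin >= spec$disk_radii[1] & dmin <= spec$disk_radii[2]
    if (!any(keep))
      stop(sprintf("empty disk annulus for radii [%g, %g] cells",
                   spec$disk_radii[1], spec$disk_radii[2]))
    candidates <- candidates[keep]
  } else if (spec$pa_strategy == "stratified") {
    bins <- integer(g$n_rows * g$n_cols)
    for (nm in env$climate) {
      v <- as.vector(env$layers[[nm]])
      br <- unique(stats::quantile(v[usable], probs = seq(0, 1, length.out = n_bins + 1),
                                   na.rm = TRUE))
      b <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
      bins <- bins * (n_bins + 1L) + b
    }
    occupied <- unique(bins[pres_cells])
    candidates <- candidates[!(bins[candidates] %in% occupied)]
    if (!length(candidates))
      stop("no environmental bin is free of presences")
  }
  n <- if (identical(spec$pa_n, "equal")) nrow(occ) else as.integer(spec$pa_n)
  if (n < 1L) stop("pseudo-absence count must be >= 1")
  with_seed(seed, {
    cells <- if (n <= length(candidates))
      sample(candidates, n) else sample(candidates, n, replace = TRUE)
    row <- ((cells - 1L) %% g$n_rows) + 1L
    col <- ((cells - 1L) %/% g$n_rows) + 1L
    data.frame(row = row, col = col,
               lon = cell_lons(g)[col], lat = cell_lats(g)[row])
  })
}

#' Fit cross-validated model replicates for one species and learner
#'
#' Each replicate draws an independent random split of the presences and of
#' the pseudo-absences into training and holdout fractions, trains the
#' learner on the training rows, and stores holdout discrimination and
#' calibration metrics (AUC, CBI, calibration statistic) together with the
#' holdout scores. Pseudo-absences are down-weighted so that the presence
#' and absence weight sums are equal. A replicate whose learner fails is
#' skipped with a warning; the run continues unless every replicate fails.
#'
#' @param learner a [learner_spec()].
#' @param presences thinned [occurrence_set()] for the species.
#' @param absences pseudo-absence points from [draw_pseudo_absences()].
#' @param env an [env_stack()].
#' @param n_replicates number of replicates.
#' @param train_frac training fraction of each class.
#' @param seed integer seed.
#' @param vars predictor layer names (default: every layer except
#'   elevation-derived duplicates is left to the caller; all layers).
#' @param species species id recorded in each fit.
#' @return list of `replicate_fit` objects.
#' @export
fit_replicates <- function(learner, presences, absences, env,
                           n_replicates = 100, train_frac = 0.7, seed = 1L,
                           vars = names(env$layers),
                           species = presences$species[1L]) {
  if (nrow(presences) < 10L) stop("at least 10 presences are required")
  g <- env$grid
  pidx <- cell_index(g, presences$lon, presences$lat)
  xp <- env_values(env, pidx$row, pidx$col, vars)
  xa <- env_values(env, absences$row, absences$col, vars)
  x <- rbind(xp, xa)
  y <- c(rep(1L, nrow(xp)), rep(0L, nrow(xa)))
  w <- c(rep(1, nrow(xp)), rep(nrow(xp) / nrow(xa), nrow(xa)))
  np <- nrow(xp)
  na_ <- nrow(xa)
  fits <- vector("list", n_replicates)
  with_seed(seed, {
    for (i in seq_len(n_replicates)) {
      tr_p <- sample.int(np, round(train_frac * np))
      tr_a <- sample.int(na_, round(train_frac * na_))
      train <- c(tr_p, np + tr_a)
      hold <- setdiff(seq_len(np + na_), train)
      fit_i <- tryCatch({
        model <- learner$fit(x[train, , drop = FALSE], y[train], w[train])
        sc <- model(x[hold, , drop = FALSE])
        yh <- y[hold]
        wh <- w[hold]
        m_auc <- auc(sc, yh)
        m_cbi <- tryCatch(boyce_index(sc[yh == 1L], sc[yh == 0L]),
                          error = function(e) NA_real_)
        m_cal <- if (learner$presence_only) NA_real_ else
          calibration_statistic(sc, yh, weights = wh)
        structure(list(species = species, learner = learner$name,
                       replicate = i, model = model, vars = vars,
                       metrics = c(auc = m_auc, cbi = m_cbi, cal = m_cal),
                       train = train, holdout = hold,
                       holdout_scores = sc, holdout_labels = yh),
                  class = "replicate_fit")
      }, error = function(e) {
        warning(sprintf("replicate %d of %s failed: %s", i, learner$name,
                        conditionMessage(e)))
        NULL
      })
      fits[[i]] <- fit_i
    }
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) stop("all replicates failed for learner ", learner$name)
  fits
}

#' Tabulate replicate holdout metrics
#'
#' @param fits list of `replicate_fit` objects.
#' @return data.frame with columns `species`, `learner`, `replicate`,
#'   `auc`, `cbi`, `cal`.
#' @export
replicate_metrics <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(species = f$species, learner = f$learner,
               replicate = f$replicate,
               auc = f$metrics[["auc"]], cbi = f$metrics[["cbi"]],
               cal = f$metrics[["cal"]])))
}

#' Replicate-mean metrics per learner
#'
#' @param fits list of `replicate_fit` objects (one species).
#' @return data.frame with columns `learner`, `auc`, `cbi`, `cal`, the
#'   mean over replicates (NA metrics dropped from the mean).
#' @export
learner_mean_metrics <- function(fits) {
  m <- replicate_metrics(fits)
  agg <- stats::aggregate(m[c("auc", "cbi", "cal")],
                          by = list(learner = m$learner),
                          FUN = function(v) mean(v, na.rm = TRUE))
  agg$cal[is.nan(agg$cal)] <- NA_real_
  agg
}

#' Predict an occurrence-probability map from one replicate fit
#'
#' @param fit a `replicate_fit`.
#' @param env an [env_stack()] (present-day or clamped scenario).
#' @return probability matrix in `[0, 1]`; masked cells stay `NA`.
#' @export
predict_map <- function(fit, env) {
  missing_vars <- setdiff(fit$vars, names(env$layers))
  if (length(missing_vars))
    stop("environment lacks model variable(s): ",
         paste(missing_vars, collapse = ", "))
  tab <- env_table(env, fit$vars)
  p <- fit$model(tab[fit$vars])
  out <- matrix(NA_real_, env$grid$n_rows, env$grid$n_cols)
  out[cbind(tab$row, tab$col)] <- p
  out
}

#' Unweighted cellwise mean of probability maps
#'
#' @param maps list of co-registered numeric matrices.
#' @return matrix of cellwise means; a cell missing in any input is
#'   missing in the output.
#' @export
ensemble_mean <- function(maps) {
  if (length(maps) < 1L) stop("at least one map is required")
  d <- dim(maps[[1L]])
  for (m in maps)
    if (!identical(dim(m), d)) stop("maps are not co-registered")
  Reduce(`+`, maps) / length(maps)
}

#' Subset replicates for scenario projection
#'
#' Draws `k` replicates per learner uniformly without replacement, to keep
#' projection cost manageable while preserving the between-replicate
#' spread.
#'
#' @param fits list of `replicate_fit` objects (may span learners).
#' @param k replicates to keep per learner.
#' @param seed integer seed.
#' @return list of `replicate_fit` objects, `k` per learner, in learner
#'   order.
#' @export
select_projection_replicates <- function(fits, k = 10, seed = 1L) {
  by_learner <- split(fits, vapply(fits, `[[`, "", "learner"))
  with_seed(seed, {
    out <- lapply(by_learner, function(fl) {
      if (k > length(fl))
        stop("k = ", k, " exceeds the ", length(fl), " available replicates")
      fl[sort(sample.int(length(fl), k))]
    })
  })
  unlist(out, recursive = FALSE, use.names = FALSE)
}

#' Build a species ensemble from replicate fits
#'
#' Computes per-learner ensemble probability maps (unweighted mean over the
#' learner's replicates), the overall ensemble map (unweighted mean over
#' all retained learner x replicate maps), and per-learner maxSSS
#' binarization thresholds from the pooled holdout scores of the retained
#' replicates.
#'
#' @param fits list of `replicate_fit` objects for one species (already
#'   subset to the projection replicates if desired).
#' @param env an [env_stack()] to predict onto.
#' @param retained learner names to keep; default all present in `fits`.
#' @return object of class `species_ensemble`: list with `species`,
#'   `retained`, `learner_maps` (named list), `overall_map`, `thresholds`
#'   (named numeric), `n_replicates` (named integer).
#' @export
species_ensemble <- function(fits, env, retained = NULL) {
  learners <- vapply(fits, `[[`, "", "learner")
  if (is.null(retained)) retained <- unique(learners)
  fits <- fits[learners %in% retained]
  learners <- learners[learners %in% retained]
  if (!length(fits)) stop("no fits left after learner filtering")
  maps <- lapply(fits, predict_map, env = env)
  by_learner <- split(seq_along(fits), learners)
  learner_maps <- lapply(by_learner, function(ii) ensemble_mean(maps[ii]))
  thresholds <- vapply(by_learner, function(ii) {
    sc <- unlist(lapply(fits[ii], `[[`, "holdout_scores"))
    lb <- unlist(lapply(fits[ii], `[[`, "holdout_labels"))
    max_sss_threshold(sc, lb)
  }, 0)
  structure(list(species = fits[[1L]]$species,
                 retained = names(by_learner),
                 learner_maps = learner_maps,
                 overall_map = ensemble_mean(maps),
                 thresholds = thresholds,
                 n_replicates = vapply(by_learner, length, 0L)),
            class = "species_ensemble")
}
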