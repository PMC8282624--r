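#' Thin occurrence records to one per species per grid cell
#'
#' Records outside the grid extent (or off the optional land mask) are
#' dropped with a message. Within each species, the first record falling in
#' a cell (in input order) is kept, so thinning is deterministic.
#'
#' @param occ an [occurrence_set()].
#' @param grid a [grid_spec()].
#' @param land_mask optional logical matrix (`TRUE` = usable land); records
#'   on `FALSE`/`NA` cells are dropped.
#' @return thinned [occurrence_set()].
#' @export
thin_to_grid <- function(occ, grid, land_mask = NULL) {
  if (nrow(occ) == 0L) return(occ)
  idx <- cell_index(grid, occ$lon, occ$lat)
  keep <- !is.na(idx$row)
  if (!is.null(land_mask)) {
    on_land <- rep(FALSE, nrow(occ))
    on_land[keep] <- !is.na(land_mask[cbind(idx$row[keep], idx$col[keep])]) &
      land_mask[cbind(idx$row[keep], idx$col[keep])]
    keep <- keep & on_land
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(n_dropped, " record(s) outside the study area dropped")
  occ <- occ[keep, , drop = FALSE]
  idx <- idx[keep, , drop = FALSE]
  first <- !duplicated(paste(occ$species, idx$row, idx$col, sep = "\r"))
  out <- occ[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check the minimum-record requirement per species
#'
#' @param occ an [occurrence_set()] (normally after thinning).
#' @param minimum required record count per species.
#' @param species optional species ids to report on; defaults to the
#'   species present in `occ` (absent requested species are reported with
#'   zero records).
#' @return data.frame with columns `species`, `n_records`, `pass`.
#' @export
check_min_records <- function(occ, minimum = 200, species = NULL) {
  if (is.null(species)) species <- unique(occ$species)
  counts <- vapply(species, function(s) sum(occ$species == s), 0L)
  data.frame(species = as.character(species), n_records = counts,
             pass = counts >= minimum, row.names = NULL)
}

# VIFs of every column of a numeric matrix: diag of the inverse correlation
# matrix; a numerically singular system marks the involved columns Inf.
vif_values <- function(x) {
  r <- stats::cor(x)
  v <- tryCatch(diag(chol2inv(chol(r))), error = function(e) NULL)
  if (!is.null(v) && all(is.finite(v))) {
    names(v) <- colnames(x)
    return(v)
  }
  # singular correlation matrix: fall back to per-variable R^2
  v <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(v) <- colnames(x)
  v
}

#' Stepwise variance-inflation-factor screening
#'
#' Iteratively removes the single variable with the highest VIF (the
#' inflation of its regression on all remaining variables, `1 / (1 - R^2)`)
#' until every remaining variable has VIF below the threshold. Constant
#' columns, whose VIF is undefined, are removed first with a warning.
#' When the maximum is attained by several variables (e.g. an exactly
#' collinear pair, both `Inf`), the one latest in input order is removed.
#'
#' @param samples data.frame/matrix of predictor values at occurrence and
#'   background points (rows > columns).
#' @param threshold VIF threshold; screening stops when all VIF <
#'   `threshold`.
#' @return object of class `variable_screen_result`: list with `steps`
#'   (data.frame `step`, `variable`, `vif` at removal), `retained`,
#'   `vif_retained`, `threshold`.
#' @export
vif_stepwise <- function(samples, threshold = 10) {
  x <- as.matrix(samples)
  if (ncol(x) < 2L) stop("at least two variables are required")
  if (nrow(x) <= ncol(x)) stop("more rows than variables are required")
  steps <- data.frame(step = integer(), variable = character(),
                      vif = numeric())
  const <- which(apply(x, 2L, function(v) stats::sd(v) < 1e-12))
  if (length(const)) {
    warning("constant column(s) removed (VIF undefined): ",
            paste(colnames(x)[const], collapse = ", "))
    for (j in colnames(x)[const])
      steps <- rbind(steps, data.frame(step = nrow(steps) + 1L,
                                       variable = j, vif = NA_real_))
    x <- x[, -const, drop = FALSE]
  }
  while (ncol(x) >= 2L) {
    v <- vif_values(x)
    worst <- max(v)
    if (worst < threshold) break
    drop_j <- max(which(v == worst))  # later in input order on ties
    steps <- rbind(steps, data.frame(step = nrow(steps) + 1L,
                                     variable = colnames(x)[drop_j],
                                     vif = worst))
    x <- x[, -drop_j, drop = FALSE]
  }
  vif_final <- if (ncol(x) >= 2L) vif_values(x) else
    stats::setNames(rep(1, ncol(x)), colnames(x))
  structure(list(steps = steps, retained = colnames(x),
                 vif_retained = vif_final, threshold = threshold),
            class = "variable_screen_result")
}

#' @export
print.variable_screen_result <- function(x, ...) {
  cat(sprintf("<variable_screen_result> %d removed, %d retained (threshold %g)\n",
              nrow(x$steps), length(x$retained), x$threshold))
  if (nrow(x$steps)) print(x$steps)
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Clamp scenario layers to the training range
#'
#' Values below/above the per-layer training minimum/maximum are set to the
#' boundary value, and a novelty mask records exactly where clamping
#' happened — the cells whose scenario climate has no analogue in the
#' training region.
#'
#' @param scenario an [env_stack()] of scenario layers.
#' @param ranges data.frame from [training_ranges()] (columns `layer`,
#'   `min`, `max`); every layer in `scenario` must have a stored range.
#' @return object of class `clamp_result`: list with `env` (clamped stack),
#'   `novelty` (named list of logical matrices), `novel_fraction` (named
#'   numeric), `ranges`.
#' @export
clamp_to_range <- function(scenario, ranges) {
  missing_r <- setdiff(names(scenario$layers), ranges$layer)
  if (length(missing_r))
    stop("no stored training range for layer(s): ",
         paste(missing_r, collapse = ", "))
  if (any(ranges$min > ranges$max)) stop("training range with min > max")
  layers <- scenario$layers
  novelty <- list()
  frac <- numeric()
  for (nm in names(layers)) {
    lo <- ranges$min[ranges$layer == nm]
    hi <- ranges$max[ranges$layer == nm]
    x <- layers[[nm]]
    nov <- !is.na(x) & (x < lo | x > hi)
    x[!is.na(x) & x < lo] <- lo
    x[!is.na(x) & x > hi] <- hi
    layers[[nm]] <- x
    novelty[[nm]] <- nov
    frac[nm] <- mean(nov[!is.na(x)])
  }
  structure(list(env = env_stack(scenario$grid, layers,
                                 climate = scenario$climate),
                 novelty = novelty, novel_fraction = frac, ranges = ranges),
            class = "clamp_result")
}
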