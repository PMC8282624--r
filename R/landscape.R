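# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Separable Gaussian smoothing of a matrix; kernel weights renormalized at
# the edges so the filter is a true local average everywhere.
smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  conv_rows <- function(m) {
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m))
    wt <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      w <- k[o + r + 1L]
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      acc[ok, ] <- acc[ok, ] + w * m[src[ok], ]
      wt[ok, ] <- wt[ok, ] + w
    }
    acc / wt
  }
  t(conv_rows(t(conv_rows(m))))
}

# Smooth standard-normal-ish random field: filtered white noise rescaled to
# zero mean and unit variance (degenerate flat fields are left at zero).
random_field <- function(n_rows, n_cols, corr_length) {
  f <- smooth2d(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                corr_length)
  s <- stats::sd(as.vector(f))
  if (is.na(s) || s < 1e-12) return(matrix(0, n_rows, n_cols))
  (f - mean(f)) / s
}

#' Parameters for the virtual landscape generator
#'
#' Defaults emulate a Central-American-like domain: a mountain ridge
#' reaching ~3000 m, sea-level temperatures near 28 degC with a standard
#' adiabatic lapse, precipitation declining from the wet south-east to the
#' dry north-west, and smooth (spatially autocorrelated) soil fields.
#'
#' @param lapse_rate temperature lapse rate, degC per m of elevation
#'   (>= 0).
#' @param corr_length autocorrelation length of the random fields, in cells.
#' @param elev_range maximum elevation of the smooth random component (m).
#' @param ridge_height additional height of a north-south ridge (m); 0
#'   disables the ridge.
#' @param ridge_width ridge half-width as a fraction of the longitudinal
#'   extent.
#' @param t_sealevel mean sea-level temperature (degC).
#' @param t_noise spatial standard deviation of the sea-level temperature
#'   field (degC).
#' @param precip_north,precip_south annual precipitation at the northern and
#'   southern extents (mm); a linear latitudinal gradient joins them.
#' @param precip_noise spatial standard deviation of the precipitation noise
#'   field (mm).
#' @param seasonality_mean,seasonality_noise mean and spatial standard
#'   deviation of precipitation seasonality (percent).
#' @param soil_noise spatial standard deviation of the soil fields around
#'   their mid-range values.
#' @return named list of generator parameters.
#' @export
landscape_params <- function(lapse_rate = 0.0065, corr_length = 8,
                             elev_range = 1200, ridge_height = 2200,
                             ridge_width = 0.18,
                             t_sealevel = 28, t_noise = 0.8,
                             precip_north = 900, precip_south = 3200,
                             precip_noise = 250,
                             seasonality_mean = 55, seasonality_noise = 12,
                             soil_noise = 1) {
  as.list(environment())
}

#' Generate a virtual environmental stack
#'
#' Builds spatially autocorrelated predictor layers with known structure:
#' elevation as a non-negative smooth random field plus an optional
#' north-south ridge; temperature as a smooth sea-level field minus
#' `lapse_rate * elevation`; precipitation as a latitudinal gradient plus
#' smooth noise; precipitation seasonality, soil sand/clay fractions and
#' soil pH as bounded smooth fields; and slope (degrees) derived from
#' elevation by centred finite differences on the spherical grid.
#'
#' @param grid a [grid_spec()].
#' @param params generator parameters from [landscape_params()].
#' @param seed integer seed; the result is reproducible bitwise.
#' @return an [env_stack()] with layers `temperature`, `precipitation`,
#'   `precip_seasonality`, `soil_sand`, `soil_clay`, `soil_ph`,
#'   `elevation`, `slope`.
#' @export
generate_landscape <- function(grid, params = landscape_params(), seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  p <- utils::modifyList(landscape_params(), params)
  if (p$lapse_rate < 0) stop("lapse_rate must be >= 0")
  nr <- grid$n_rows
  nc <- grid$n_cols
  with_seed(seed, {
    base <- random_field(nr, nc, p$corr_length)
    elev <- p$elev_range * (base - min(base)) / max(diff(range(base)), 1e-12)
    if (p$ridge_height > 0) {
      lon_frac <- (seq_len(nc) - 0.5) / nc
      ridge <- p$ridge_height *
        exp(-((lon_frac - 0.5) / p$ridge_width)^2)
      elev <- elev + matrix(ridge, nr, nc, byrow = TRUE)
    }
    temp <- p$t_sealevel + p$t_noise * random_field(nr, nc, p$corr_length) -
      p$lapse_rate * elev
    latw <- (grid$lat_max - cell_lats(grid)) / (grid$lat_max - grid$lat_min)
    precip <- matrix(p$precip_north + latw * (p$precip_south - p$precip_north),
                     nr, nc) +
      p$precip_noise * random_field(nr, nc, p$corr_length)
    precip[precip < 0] <- 0
    seas <- p$seasonality_mean +
      p$seasonality_noise * random_field(nr, nc, p$corr_length)
    seas[seas < 0] <- 0
    seas[seas > 100] <- 100
    bounded_field <- function(lo, hi) {
      mid <- (lo + hi) / 2
      f <- mid + (hi - lo) / 6 * p$soil_noise * random_field(nr, nc, p$corr_length)
      pmin(pmax(f, lo), hi)  # f first so matrix dims survive pmin/pmax
    }
    sand <- bounded_field(10, 90)
    clay <- bounded_field(5, 60)
    ph <- bounded_field(4.5, 7.5)
    env_stack(grid, list(
      temperature = temp, precipitation = precip,
      precip_seasonality = seas,
      soil_sand = sand, soil_clay = clay, soil_ph = ph,
      elevation = elev, slope = slope_from_elevation(elev, grid)))
  })
}

# Slope (degrees) from elevation by centred finite differences; cell sizes
# converted to metres with a cos-latitude correction for the x spacing.
slope_from_elevation <- function(elev, grid) {
  nr <- nrow(elev)
  nc <- ncol(elev)
  m_per_deg <- 111320
  dy <- grid$dlat * m_per_deg
  dx <- grid$dlon * m_per_deg * cos(cell_lats(grid) * pi / 180)
  up <- elev[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- elev[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- elev[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- elev[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  span_y <- c(1, rep(2, max(nr - 2L, 0L)), 1)[seq_len(nr)]
  span_x <- c(1, rep(2, max(nc - 2L, 0L)), 1)[seq_len(nc)]
  gy <- (up - dn) / (span_y * dy)
  gx <- (rt - lf) / rep(span_x, each = nr) / dx  # dx recycles down columns
  atan(sqrt(gx^2 + gy^2)) * 180 / pi
}

#' Specify a virtual species niche
#'
#' The ground-truth suitability of a virtual species is a product of
#' independent Gaussian responses, one per referenced environmental
#' variable, scaled by a maximum occurrence probability. This analytically
#' simple form makes every downstream estimate checkable against a known
#' truth.
#'
#' @param species species identifier.
#' @param optima named numeric vector of niche optima (variable units).
#' @param breadths named numeric vector of niche breadths (Gaussian
#'   standard deviations, same units, > 0); names must match `optima`.
#' @param prob_max maximum occurrence probability in (0, 1].
#' @return object of class `niche_spec`.
#' @export
niche_spec <- function(species, optima, breadths, prob_max = 1) {
  if (length(optima) < 1L) stop("at least one niche variable is required")
  if (!setequal(names(optima), names(breadths)))
    stop("optima and breadths must reference the same variables")
  breadths <- breadths[names(optima)]
  if (any(breadths <= 0)) stop("niche breadths must be strictly positive")
  if (prob_max <= 0 || prob_max > 1) stop("prob_max must be in (0, 1]")
  structure(list(species = species, optima = optima, breadths = breadths,
                 prob_max = prob_max),
            class = "niche_spec")
}

#' Ground-truth suitability of a virtual species
#'
#' @param env an [env_stack()].
#' @param niche a [niche_spec()].
#' @return matrix of occurrence probabilities in `[0, prob_max]`; masked
#'   cells are `NA`.
#' @export
true_suitability <- function(env, niche) {
  missing_vars <- setdiff(names(niche$optima), names(env$layers))
  if (length(missing_vars))
    stop("niche variable(s) not in the environment stack: ",
         paste(missing_vars, collapse = ", "))
  out <- matrix(niche$prob_max, env$grid$n_rows, env$grid$n_cols)
  for (v in names(niche$optima)) {
    x <- env$layers[[v]]
    out <- out * exp(-(x - niche$optima[[v]])^2 / (2 * niche$breadths[[v]]^2))
  }
  out
}

#' Construct an occurrence table
#'
#' @param species character vector of species ids.
#' @param lon,lat record coordinates (decimal degrees).
#' @param provenance `"synthetic"` or `"file"`.
#' @return data.frame of class `occurrence_set` with columns
#'   `species`, `lon`, `lat`.
#' @export
occurrence_set <- function(species, lon, lat, provenance = "synthetic") {
  out <- data.frame(species = as.character(species), lon = lon, lat = lat)
  attr(out, "provenance") <- provenance
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Sample virtual occurrence records
#'
#' Cells are drawn (with replacement) with probability proportional to
#' `true suitability x bias`; record coordinates are jittered uniformly
#' within the sampled cell so that grid thinning is exercised downstream.
#'
#' @param env an [env_stack()].
#' @param niche a [niche_spec()].
#' @param n number of records (>= 1).
#' @param bias optional non-negative sampling-effort matrix on the grid;
#'   defaults to uniform effort.
#' @param seed integer seed.
#' @return an [occurrence_set()] with exactly `n` rows.
#' @export
sample_occurrences <- function(env, niche, n, bias = NULL, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  g <- env$grid
  suit <- true_suitability(env, niche)
  w <- if (is.null(bias)) suit else suit * bias
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("all sampling weights are zero")
  with_seed(seed, {
    cells <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
    row <- ((cells - 1L) %% g$n_rows) + 1L
    col <- ((cells - 1L) %/% g$n_rows) + 1L
    lat_north <- g$lat_max - (row - 1L) * g$dlat
    lon_west <- g$lon_min + (col - 1L) * g$dlon
    occurrence_set(rep(niche$species, n),
                   lon = lon_west + stats::runif(n) * g$dlon,
                   lat = lat_north - stats::runif(n) * g$dlat)
  })
}

#' Specify a climate-change scenario delta
#'
#' A delta transforms each named climate layer cellwise as
#' `x * factor + offset`; offsets and factors may be scalars or full grids.
#' Non-climate layers (elevation, slope, soils) can never be targeted.
#'
#' @param label scenario label, e.g. `"RCP8.5-like"`.
#' @param offset named list/vector of additive offsets (layer units).
#' @param factor named list/vector of multiplicative factors (> 0).
#' @return object of class `climate_delta`.
#' @export
climate_delta <- function(label, offset = list(), factor = list()) {
  factor <- as.list(factor)
  offset <- as.list(offset)
  for (nm in names(factor))
    if (any(unlist(factor[[nm]]) <= 0))
      stop("multiplicative factors must be > 0 (layer '", nm, "')")
  structure(list(label = label, offset = offset, factor = factor),
            class = "climate_delta")
}

#' Apply a climate delta to an environment stack
#'
#' @param env an [env_stack()].
#' @param delta a [climate_delta()].
#' @return a new [env_stack()]; the input is not modified and non-climate
#'   layers are copied unchanged.
#' @export
apply_climate_delta <- function(env, delta) {
  stopifnot(inherits(delta, "climate_delta"))
  touched <- union(names(delta$offset), names(delta$factor))
  bad <- setdiff(touched, env$climate)
  if (length(bad))
    stop("delta targets non-climate layer(s): ", paste(bad, collapse = ", "))
  layers <- env$layers
  for (nm in touched) {
    fac <- if (nm %in% names(delta$factor)) delta$factor[[nm]] else 1
    off <- if (nm %in% names(delta$offset)) delta$offset[[nm]] else 0
    layers[[nm]] <- layers[[nm]] * fac + off
  }
  env_stack(env$grid, layers, climate = env$climate)
}
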