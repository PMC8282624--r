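#' Latitude-altitude points of PFT presences
#'
#' One row per present cell: the cell-center latitude and the cell's
#' elevation. These point clouds feed the density and boundary-shift
#' diagnostics.
#'
#' @param presence logical presence matrix (e.g. `pft_result$presence`).
#' @param elevation elevation matrix (m).
#' @param grid the [grid_spec()].
#' @return data.frame with columns `lat`, `alt` (empty when no cell is
#'   present).
#' @export
presence_lat_alt <- function(presence, elevation, grid) {
  stopifnot(identical(dim(presence), dim(elevation)),
            identical(dim(presence), c(grid$n_rows, grid$n_cols)))
  idx <- which(presence & !is.na(elevation), arr.ind = TRUE)
  data.frame(lat = cell_lats(grid)[idx[, 1L]],
             alt = elevation[idx])
}

#' Gaussian kernel density over latitude x altitude
#'
#' A 2-D kernel density estimate of the presence cloud, evaluated on a
#' regular grid extended 4 bandwidths beyond the data range so the density
#' integrates to ~1 over the evaluation domain.
#'
#' @param points data.frame with columns `lat`, `alt`.
#' @param bandwidths kernel standard deviations `c(degrees, m)`; default
#'   Silverman's rule per axis.
#' @param n evaluation grid size per axis.
#' @return list with `lat`, `alt` (axis vectors) and `density` (matrix,
#'   latitude on rows).
#' @export
density_cloud <- function(points, bandwidths = NULL, n = 128) {
  if (nrow(points) < 1L) stop("at least one point is required")
  if (is.null(bandwidths))
    bandwidths <- c(max(stats::bw.nrd0(points$lat), 1e-6),
                    max(stats::bw.nrd0(points$alt), 1e-6))
  if (any(bandwidths <= 0)) stop("bandwidths must be > 0")
  lims <- c(range(points$lat) + c(-4, 4) * bandwidths[1],
            range(points$alt) + c(-4, 4) * bandwidths[2])
  # MASS::kde2d uses a kernel standard deviation of h/4
  k <- MASS::kde2d(points$lat, points$alt, h = 4 * bandwidths,
                   n = n, lims = lims)
  list(lat = k$x, alt = k$y, density = k$z)
}

#' Lower-boundary altitude of a presence cloud
#'
#' @param points data.frame with column `alt`.
#' @param quantile lower-boundary quantile of the presence altitudes.
#' @return altitude in m.
#' @export
lower_boundary <- function(points, quantile = 0.05) {
  if (nrow(points) == 0L) stop("empty presence set")
  unname(stats::quantile(points$alt, probs = quantile, type = 7))
}

#' Upslope shift of the lower range boundary
#'
#' The lower boundary is the stated altitude quantile of the presence
#' cells; the shift is scenario minus present (positive = upslope), the
#' indicator of mountaintop-extinction risk.
#'
#' @param points_present,points_scenario data.frames with column `alt`.
#' @param quantile lower-boundary quantile.
#' @return shift in m.
#' @export
boundary_shift <- function(points_present, points_scenario, quantile = 0.05) {
  lower_boundary(points_scenario, quantile) -
    lower_boundary(points_present, quantile)
}

#' Latitudinal density modes of a presence cloud
#'
#' A 1-D Gaussian kernel density over latitude; modes are local maxima
#' whose topographic prominence (height above the higher of the two
#' deepest valleys separating the peak from higher terrain) reaches
#' `min_prominence` times the global maximum. Divergence of a PFT into two
#' or more separate density centres shows up as `n_modes >= 2`.
#'
#' @param points data.frame with column `lat` (>= 2 rows).
#' @param bandwidth kernel standard deviation in degrees; default
#'   Silverman's rule.
#' @param min_prominence prominence threshold as a fraction of the global
#'   density maximum.
#' @param n evaluation points.
#' @return list with `n_modes` and `locations` (degrees, ascending).
#' @export
latitudinal_modes <- function(points, bandwidth = NULL, min_prominence = 0.1,
                              n = 512) {
  if (nrow(points) < 2L) stop("at least two points are required")
  if (is.null(bandwidth)) bandwidth <- max(stats::bw.nrd0(points$lat), 1e-6)
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  d <- stats::density(points$lat, bw = bandwidth, n = n)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2L) + 1L
  if (!length(peaks)) return(list(n_modes = 0L, locations = numeric()))
  prominence <- vapply(peaks, function(p) {
    base <- -Inf
    for (dir in c(-1L, 1L)) {
      i <- p
      low <- y[p]
      repeat {
        i <- i + dir
        if (i < 1L || i > length(y)) break
        if (y[i] > y[p]) break
        low <- min(low, y[i])
      }
      base <- max(base, low)
    }
    y[p] - base
  }, 0)
  keep <- prominence >= min_prominence * max(y)
  list(n_modes = sum(keep), locations = sort(d$x[peaks[keep]]))
}
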