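#' Define a regular geographic grid
#'
#' All rasters in pftshift live on a plain geographic (longitude/latitude)
#' grid described by a `grid_spec`. Conventions, used everywhere in the
#' package: north-up storage (row 1 is the northernmost row), cell-center
#' registration, and half-open cell intervals — a cell owns latitudes in
#' `[north edge, south edge)` and longitudes in `[west edge, east edge)`,
#' with points exactly on the outer north/west extent assigned to the first
#' row/column.
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param lat_min,lat_max,lon_min,lon_max extent in decimal degrees.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, lat_min, lat_max, lon_min, lon_max) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers")
  if (!(lat_max > lat_min)) stop("lat_max must exceed lat_min")
  if (!(lon_max > lon_min)) stop("lon_max must exceed lon_min")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         lat_min = lat_min, lat_max = lat_max,
         lon_min = lon_min, lon_max = lon_max,
         dlat = (lat_max - lat_min) / n_rows,
         dlon = (lon_max - lon_min) / n_cols),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, lat [%g, %g], lon [%g, %g], cell %g x %g deg\n",
              x$n_rows, x$n_cols, x$lat_min, x$lat_max, x$lon_min, x$lon_max,
              x$dlat, x$dlon))
  invisible(x)
}

#' Cell-center latitudes (row 1 = northernmost) and longitudes
#' @param grid a [grid_spec()].
#' @return numeric vector of cell-center coordinates.
#' @export
cell_lats <- function(grid) grid$lat_max - (seq_len(grid$n_rows) - 0.5) * grid$dlat

#' @rdname cell_lats
#' @export
cell_lons <- function(grid) grid$lon_min + (seq_len(grid$n_cols) - 0.5) * grid$dlon

#' Map point coordinates to grid cells
#'
#' Uses the half-open cell convention documented in [grid_spec()]. Points
#' outside the extent get `NA` indices.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat point coordinates (degrees), recycled to common length.
#' @return data.frame with integer columns `row`, `col`.
#' @export
cell_index <- function(grid, lon, lat) {
  inside <- lon >= grid$lon_min & lon <= grid$lon_max &
    lat >= grid$lat_min & lat <= grid$lat_max
  row <- floor((grid$lat_max - lat) / grid$dlat) + 1L
  col <- floor((lon - grid$lon_min) / grid$dlon) + 1L
  # southern/eastern extent edges belong to the last row/column
  row <- pmin(row, grid$n_rows)
  col <- pmin(col, grid$n_cols)
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Spherical cell areas
#'
#' Cell areas from spherical geometry (exact integral of the cosine of
#' latitude across each cell), so that area statistics are meaningful on
#' grids spanning many degrees of latitude.
#'
#' @param grid a [grid_spec()].
#' @param radius_km sphere radius; defaults to the mean Earth radius.
#' @return matrix (`n_rows` x `n_cols`) of areas in km^2.
#' @export
cell_area_km2 <- function(grid, radius_km = 6371.0088) {
  lat_top <- grid$lat_max - (seq_len(grid$n_rows) - 1L) * grid$dlat
  lat_bot <- lat_top - grid$dlat
  deg2rad <- pi / 180
  band <- radius_km^2 * (grid$dlon * deg2rad) *
    (sin(lat_top * deg2rad) - sin(lat_bot * deg2rad))
  matrix(band, nrow = grid$n_rows, ncol = grid$n_cols)
}
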