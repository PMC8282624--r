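#' Bundle co-registered environmental layers
#'
#' An `env_stack` holds named 2-D numeric layers sharing one [grid_spec()].
#' An `elevation` layer is mandatory. Missing cells (e.g. ocean) are `NA`
#' and must be `NA` in every layer; the common missing-value mask is checked
#' at construction.
#'
#' @param grid a [grid_spec()].
#' @param layers named list of numeric matrices with dimensions
#'   `n_rows x n_cols`; must contain `"elevation"`.
#' @param climate character vector naming the layers that climate-change
#'   deltas may modify. Defaults to every layer except elevation, slope and
#'   soil variables.
#' @return object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, climate = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named")
  if (!"elevation" %in% names(layers))
    stop("an 'elevation' layer is required")
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || !identical(dim(m), c(grid$n_rows, grid$n_cols)))
      stop("layer '", nm, "' does not match the grid dimensions")
    storage.mode(layers[[nm]]) <- "double"
  }
  mask <- is.na(layers[[1L]])
  for (nm in names(layers))
    if (!identical(is.na(layers[[nm]]), mask))
      stop("layer '", nm, "' has a different missing-value mask")
  if (is.null(climate)) {
    static <- c("elevation", "slope", "soil_sand", "soil_clay", "soil_ph")
    climate <- setdiff(names(layers), static)
  }
  if (!all(climate %in% names(layers)))
    stop("climate layer names not present in the stack: ",
         paste(setdiff(climate, names(layers)), collapse = ", "))
  structure(list(grid = grid, layers = layers, climate = climate),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers on %d x %d grid (%d masked cells)\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              sum(is.na(x$layers[[1L]]))))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat("  climate:", paste(x$climate, collapse = ", "), "\n")
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

#' Extract layer values at grid cells
#'
#' @param env an [env_stack()].
#' @param row,col integer cell indices (recycled to common length).
#' @param vars layer names to extract; default all.
#' @return data.frame, one row per (row, col) pair, one column per layer.
#' @export
env_values <- function(env, row, col, vars = names(env$layers)) {
  idx <- cbind(row, col)
  out <- lapply(env$layers[vars], function(m) m[idx])
  as.data.frame(out, optional = TRUE)
}

#' Table of all non-missing cells with coordinates and layer values
#'
#' @param env an [env_stack()].
#' @param vars layer names to include; default all.
#' @return data.frame with `row`, `col`, `lon`, `lat` and one column per
#'   requested layer; masked cells are omitted.
#' @export
env_table <- function(env, vars = names(env$layers)) {
  g <- env$grid
  keep <- which(!is.na(env$layers[[1L]]))
  row <- ((keep - 1L) %% g$n_rows) + 1L
  col <- ((keep - 1L) %/% g$n_rows) + 1L
  out <- data.frame(row = row, col = col,
                    lon = cell_lons(g)[col], lat = cell_lats(g)[row])
  cbind(out, env_values(env, row, col, vars))
}

#' Per-layer minima and maxima over the non-missing grid
#'
#' The training range used for clamping scenario layers: the span of values
#' present across the whole study-region grid.
#'
#' @param env an [env_stack()].
#' @return data.frame with columns `layer`, `min`, `max`.
#' @export
training_ranges <- function(env) {
  data.frame(
    layer = names(env$layers),
    min = vapply(env$layers, function(m) min(m, na.rm = TRUE), 0),
    max = vapply(env$layers, function(m) max(m, na.rm = TRUE), 0),
    row.names = NULL)
}
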