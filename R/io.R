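#' Write and read single-layer text rasters
#'
#' The package's raster interchange format is the ESRI ASCII grid: a short
#' plain-text header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize` — or `dx`/`dy` when cells are not square — and
#' `NODATA_value`) followed by the matrix in north-to-south row order,
#' matching the package's in-memory layout.
#'
#' @param mat numeric matrix (row 1 = northernmost row).
#' @param grid the [grid_spec()] the matrix lives on.
#' @param path output file path.
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(mat, grid, path, digits = 8) {
  stopifnot(identical(dim(mat), c(grid$n_rows, grid$n_cols)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$lon_min),
               sprintf("yllcorner %.10g", grid$lat_min)), con)
  if (isTRUE(all.equal(grid$dlon, grid$dlat))) {
    writeLines(sprintf("cellsize %.10g", grid$dlon), con)
  } else {
    writeLines(c(sprintf("dx %.10g", grid$dlon),
                 sprintf("dy %.10g", grid$dlat)), con)
  }
  writeLines("NODATA_value -9999", con)
  m <- mat
  m[is.na(m)] <- -9999
  utils::write.table(signif(m, digits), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return for `read_ascii_grid`: list with `mat` and `grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 7L)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2L]))))
      break
    if (!grepl("^[A-Za-z_]+$", parts[1L])) break
    header[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    n_header <- n_header + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(req %in% names(header)))
    stop("malformed ASCII grid header in ", path, " (line ", n_header + 1L,
         "): need ", paste(req, collapse = ", "))
  dx <- if ("cellsize" %in% names(header)) header$cellsize else header$dx
  dy <- if ("cellsize" %in% names(header)) header$cellsize else header$dy
  if (is.null(dx) || is.null(dy))
    stop("malformed ASCII grid header in ", path, ": no cell size")
  vals <- scan(path, skip = n_header, quiet = TRUE)
  nr <- as.integer(header$nrows)
  nc <- as.integer(header$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid ", path, " has ", length(vals), " values, expected ",
         nr * nc)
  mat <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(header$nodata_value)) mat[mat == header$nodata_value] <- NA
  grid <- grid_spec(nr, nc,
                    lat_min = header$yllcorner,
                    lat_max = header$yllcorner + nr * dy,
                    lon_min = header$xllcorner,
                    lon_max = header$xllcorner + nc * dx)
  list(mat = mat, grid = grid)
}

#' Write and read an environment stack as text rasters
#'
#' One ASCII grid per layer (`<prefix><layer>.asc`) plus a JSON sidecar
#' (`<prefix>stack.json`) recording layer order and climate-layer names.
#'
#' @param env an [env_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the sidecar path (write) or an [env_stack()] (read).
#' @export
write_env_stack <- function(env, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(env$layers))
    write_ascii_grid(env$layers[[nm]], env$grid,
                     file.path(dir, paste0(prefix, nm, ".asc")))
  sidecar <- file.path(dir, paste0(prefix, "stack.json"))
  jsonlite::write_json(list(layers = names(env$layers),
                            climate = env$climate),
                       sidecar, auto_unbox = FALSE)
  invisible(sidecar)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(dir, prefix = "") {
  sidecar <- file.path(dir, paste0(prefix, "stack.json"))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  layers <- list()
  grid <- NULL
  for (nm in meta$layers) {
    r <- read_ascii_grid(file.path(dir, paste0(prefix, nm, ".asc")))
    layers[[nm]] <- r$mat
    grid <- r$grid
  }
  env_stack(grid, layers, climate = meta$climate)
}

#' Write and read occurrence tables
#'
#' Plain CSV with header `species,lon,lat`.
#'
#' @param occ an [occurrence_set()].
#' @param path CSV path.
#' @return `path` invisibly (write) or an [occurrence_set()] (read).
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ[c("species", "lon", "lat")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "lon", "lat")
  if (!all(req %in% names(df)))
    stop("occurrence CSV ", path, " must have columns species, lon, lat")
  occurrence_set(df$species, df$lon, df$lat, provenance = "file")
}
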