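#' Dominant-PFT classification per grid cell
#'
#' In each cell, candidate PFTs are those whose presence mask (bS-SDM >=
#' presence threshold) is true; the cell is labelled with the candidate of
#' highest richness (summed occurrence probability). Cells with no
#' candidate are labelled `"None"`. Exact richness ties are broken by the
#' canonical PFT order and flagged. Masked cells stay `NA`.
#'
#' @param pft_results list of [pft_result()] objects (co-registered).
#' @param order canonical PFT order for tie-breaking; defaults to the
#'   order of `pft_results`.
#' @param candidates_only if `FALSE`, the argmax runs over all PFTs
#'   regardless of their presence mask (the `"None"` rule is unchanged).
#' @return object of class `dominance_map`: list with `labels` (character
#'   matrix over PFT names and `"None"`), `classes` (canonical class
#'   vector), `ties` (logical matrix), `grid_dim`.
#' @export
dominant_pft <- function(pft_results, order = NULL, candidates_only = TRUE) {
  if (!length(pft_results)) stop("at least one PFT result is required")
  pfts <- vapply(pft_results, `[[`, "", "pft")
  if (is.null(order)) order <- pfts
  stopifnot(setequal(order, pfts))
  pft_results <- pft_results[match(order, pfts)]
  d <- dim(pft_results[[1L]]$richness)
  n_pft <- length(pft_results)
  rich <- array(NA_real_, c(d, n_pft))
  pres <- array(FALSE, c(d, n_pft))
  for (i in seq_len(n_pft)) {
    if (!identical(dim(pft_results[[i]]$richness), d))
      stop("PFT results are not co-registered")
    rich[, , i] <- pft_results[[i]]$richness
    pres[, , i] <- pft_results[[i]]$presence
  }
  masked <- is.na(rich[, , 1L])
  score <- rich
  if (candidates_only) score[!pres] <- -Inf
  any_candidate <- apply(pres, c(1, 2), any)
  labels <- matrix(NA_character_, d[1], d[2])
  ties <- matrix(FALSE, d[1], d[2])
  best <- apply(score, c(1, 2), function(v) {
    if (all(!is.finite(v))) return(c(0, 0))
    m <- max(v)
    c(which(v == m)[1L], sum(v == m))
  })
  sel <- best[1, , ]
  n_max <- best[2, , ]
  has_label <- !masked & (if (candidates_only) any_candidate else n_max > 0)
  labels[!masked] <- "None"
  labels[has_label] <- order[sel[has_label]]
  ties[has_label] <- n_max[has_label] > 1
  structure(list(labels = labels, classes = c(order, "None"),
                 ties = ties, grid_dim = d),
            class = "dominance_map")
}

#' Area covered by each dominance class
#'
#' @param dom a [dominant_pft()] result.
#' @param cell_area matrix of per-cell areas (km^2), e.g. from
#'   [cell_area_km2()]; default unit cell areas (fractions then equal cell
#'   fractions).
#' @return data.frame with columns `class`, `area_km2`, `fraction`;
#'   fractions over non-missing cells sum to 1.
#' @export
area_fractions <- function(dom, cell_area = NULL) {
  if (is.null(cell_area))
    cell_area <- matrix(1, dom$grid_dim[1], dom$grid_dim[2])
  if (any(cell_area <= 0, na.rm = TRUE)) stop("cell areas must be positive")
  ok <- !is.na(dom$labels)
  area <- vapply(dom$classes, function(cl)
    sum(cell_area[ok & dom$labels == cl]), 0)
  data.frame(class = dom$classes, area_km2 = area,
             fraction = area / sum(area), row.names = NULL)
}

#' Present-to-future dominance transition flows
#'
#' @param dom_present,dom_future [dominant_pft()] results on the same grid.
#' @param cell_area optional per-cell area matrix; default counts cells.
#' @return square matrix; entry (i, j) is the area (or cell count) labelled
#'   class i at present and class j in the scenario, over jointly
#'   non-missing cells.
#' @export
transition_flows <- function(dom_present, dom_future, cell_area = NULL) {
  if (!identical(dom_present$grid_dim, dom_future$grid_dim))
    stop("dominance maps are on different grids")
  classes <- union(dom_present$classes, dom_future$classes)
  if (is.null(cell_area))
    cell_area <- matrix(1, dom_present$grid_dim[1], dom_present$grid_dim[2])
  ok <- !is.na(dom_present$labels) & !is.na(dom_future$labels)
  flow <- matrix(0, length(classes), length(classes),
                 dimnames = list(present = classes, future = classes))
  from <- factor(dom_present$labels[ok], levels = classes)
  to <- factor(dom_future$labels[ok], levels = classes)
  w <- cell_area[ok]
  for (k in seq_along(from))
    flow[from[k], to[k]] <- flow[from[k], to[k]] + w[k]
  flow
}
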