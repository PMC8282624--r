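#' Fragmentation class labels
#'
#' Canonical class order used by the fragmentation maps: the five in-PFT
#' classes, the scenario-loss overlay, and background.
#' @export
fragmentation_classes <- function() {
  c("interior", "perforated", "edge", "transitional", "patch",
    "area-loss", "background")
}

#' Moving-window cover (Pf) and connectivity (Pff)
#'
#' Within a 3x3 window centred on each cell, `Pf` is the proportion of
#' in-window, in-map cells covered by the PFT, and `Pff` the conditional
#' probability that a neighbour of a covered cell is covered, estimated
#' over unordered cardinally adjacent cell pairs as `2*FF / (2*FF + FN)`
#' (FF = both covered, FN = mixed). `Pff` is `NA` where no pair involves a
#' covered cell. At map borders the window is truncated, so `Pf` remains a
#' true proportion of observed cells.
#'
#' @param binary 0/1 matrix (NA = no data).
#' @return list with matrices `pf` and `pff`.
#' @export
pf_pff <- function(binary) {
  if (!all(binary %in% c(0, 1) | is.na(binary)))
    stop("input must be binary (0/1)")
  nr <- nrow(binary)
  nc <- ncol(binary)
  pf <- matrix(NA_real_, nr, nc)
  pff <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - 1L):min(nr, i + 1L)
    for (j in seq_len(nc)) {
      cj <- max(1L, j - 1L):min(nc, j + 1L)
      w <- binary[ri, cj, drop = FALSE]
      obs <- !is.na(w)
      if (!any(obs)) next
      pf[i, j] <- mean(w[obs])
      ff <- 0L
      fn <- 0L
      wr <- nrow(w)
      wc <- ncol(w)
      if (wc > 1L) for (a in seq_len(wr)) for (b in seq_len(wc - 1L)) {
        x <- w[a, b]; yv <- w[a, b + 1L]
        if (!is.na(x) && !is.na(yv)) {
          if (x == 1 && yv == 1) ff <- ff + 1L
          else if (x != yv) fn <- fn + 1L
        }
      }
      if (wr > 1L) for (a in seq_len(wr - 1L)) for (b in seq_len(wc)) {
        x <- w[a, b]; yv <- w[a + 1L, b]
        if (!is.na(x) && !is.na(yv)) {
          if (x == 1 && yv == 1) ff <- ff + 1L
          else if (x != yv) fn <- fn + 1L
        }
      }
      if (2L * ff + fn > 0L) pff[i, j] <- 2 * ff / (2 * ff + fn)
    }
  }
  list(pf = pf, pff = pff)
}

#' Fragmentation classification of a PFT map
#'
#' Rules applied at cells where the PFT is present in the scenario:
#' interior if `Pf = 1`; patch if `Pf < 0.4`; transitional if
#' `0.4 <= Pf <= 0.6` (the boundary values, which the strict rules leave
#' open, are assigned to transitional to keep the classes exhaustive);
#' perforated if `Pf > 0.6` and `Pf - Pff > 0`; edge if `Pf > 0.6` and
#' `Pf - Pff <= 0`. Cells absent now but present at baseline are
#' `area-loss`; cells absent in both are `background`.
#'
#' @param pf,pff matrices from [pf_pff()] on the scenario presence map.
#' @param presence_now logical/0-1 matrix of scenario presence.
#' @param presence_baseline optional logical/0-1 matrix of baseline
#'   presence (enables the area-loss overlay).
#' @param pft,scenario labels stored on the result.
#' @return object of class `fragmentation_map`: list with `classes`
#'   (factor matrix as integer codes into [fragmentation_classes()]),
#'   `levels`, `pf`, `pff`, `pft`, `scenario`.
#' @export
classify_fragmentation <- function(pf, pff, presence_now,
                                   presence_baseline = NULL,
                                   pft = NA_character_,
                                   scenario = NA_character_) {
  if (any(pf < 0 | pf > 1, na.rm = TRUE)) stop("Pf outside [0, 1]")
  now <- !is.na(presence_now) & presence_now == 1
  lev <- fragmentation_classes()
  cls <- matrix(NA_integer_, nrow(pf), ncol(pf))
  cls[] <- match("background", lev)
  if (!is.null(presence_baseline)) {
    was <- !is.na(presence_baseline) & presence_baseline == 1
    cls[!now & was] <- match("area-loss", lev)
  }
  eps <- 1e-12
  idx <- which(now)
  for (cell in idx) {
    p <- pf[cell]
    q <- pff[cell]
    cls[cell] <- if (is.na(p)) NA_integer_
    else if (p >= 1 - eps) match("interior", lev)
    else if (p < 0.4 - eps) match("patch", lev)
    else if (p <= 0.6 + eps) match("transitional", lev)
    else if (!is.na(q) && p - q > eps) match("perforated", lev)
    else match("edge", lev)
  }
  structure(list(classes = cls, levels = lev, pf = pf, pff = pff,
                 pft = pft, scenario = scenario),
            class = "fragmentation_map")
}

#' Fragmentation class areas
#'
#' @param frag a [classify_fragmentation()] result.
#' @param cell_area optional matrix of per-cell areas (km^2); default unit
#'   areas.
#' @return data.frame with columns `class`, `area_km2`, `fraction`;
#'   fractions over classified (non-background) cells sum to 1.
#' @export
fragmentation_summary <- function(frag, cell_area = NULL) {
  if (is.null(cell_area))
    cell_area <- matrix(1, nrow(frag$classes), ncol(frag$classes))
  lev <- frag$levels
  area <- vapply(seq_along(lev), function(k)
    sum(cell_area[!is.na(frag$classes) & frag$classes == k]), 0)
  keep <- lev != "background"
  frac <- rep(NA_real_, length(lev))
  tot <- sum(area[keep])
  if (tot > 0) frac[keep] <- area[keep] / tot
  data.frame(class = lev, area_km2 = area, fraction = frac,
             row.names = NULL)[keep, ]
}
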