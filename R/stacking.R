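#' maxSSS binarization threshold
#'
#' The threshold maximizing sensitivity + specificity, scanned over all
#' observed score values as candidate thresholds, with prediction positive
#' iff `score >= threshold`. Ties in the objective are broken toward the
#' smallest threshold.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical), same length.
#' @return the selected threshold.
#' @export
max_sss_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  cand <- sort(unique(scores))
  # exact integer-count objective: sens + spec = (tp*n0 + tn*n1)/(n1*n0),
  # so maximizing the numerator avoids float ties between equal objectives
  num <- vapply(cand, function(tau) {
    tp <- sum(scores >= tau & labels == 1L)
    tn <- sum(scores < tau & labels == 0L)
    tp * n0 + tn * n1
  }, 0)
  cand[which.max(num)]  # which.max returns the first (smallest) maximizer
}

#' Binarize a species ensemble by algorithm agreement
#'
#' A cell is a species presence iff at least `min_agree` learners predict a
#' probability at or above their own maxSSS threshold.
#'
#' @param maps named list of per-learner ensemble probability maps.
#' @param thresholds numeric vector of per-learner thresholds, aligned with
#'   `maps` by name or position.
#' @param min_agree minimum number of agreeing learners.
#' @return integer matrix of 0/1 (NA where masked).
#' @export
binarize_species <- function(maps, thresholds, min_agree = 3) {
  if (length(maps) < min_agree)
    stop("only ", length(maps), " learners available but min_agree = ", min_agree)
  if (length(thresholds) != length(maps))
    stop("one threshold per learner map is required")
  if (!is.null(names(maps)) && !is.null(names(thresholds)))
    thresholds <- thresholds[names(maps)]
  votes <- Reduce(`+`, Map(function(m, tau) (m >= tau) * 1L, maps,
                           as.list(thresholds)))
  (votes >= min_agree) * 1L
}

#' Stack member species probabilities into a PFT richness map
#'
#' @param maps list of member-species overall ensemble maps (values in
#'   `[0, 1]`).
#' @return cellwise sum; range `[0, n_members]`.
#' @export
stack_richness <- function(maps) {
  if (length(maps) < 1L) stop("at least one member map is required")
  d <- dim(maps[[1L]])
  for (m in maps) {
    if (!identical(dim(m), d)) stop("maps are not co-registered")
    if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE))
      stop("member maps must lie in [0, 1]")
  }
  Reduce(`+`, maps)
}

#' bS-SDM count and PFT presence mask
#'
#' The bS-SDM map is the cellwise sum of the member species' binary
#' presence maps; a PFT is present where at least `presence_min` members
#' are present, which buffers the stack against single-species outliers.
#'
#' @param binary_maps list of member binary maps (0/1, NA allowed).
#' @param presence_min minimum bS-SDM count for PFT presence.
#' @return list with `bs_sdm` (integer matrix) and `presence` (logical
#'   matrix).
#' @export
pft_presence <- function(binary_maps, presence_min = 2) {
  if (length(binary_maps) < 1L) stop("at least one member map is required")
  for (m in binary_maps)
    if (!all(m %in% c(0, 1) | is.na(m)))
      stop("member maps must be binary (0/1)")
  bs <- Reduce(`+`, lapply(binary_maps, function(m) {
    storage.mode(m) <- "double"
    m
  }))
  list(bs_sdm = bs, presence = !is.na(bs) & bs >= presence_min)
}

#' Assemble the per-PFT stacked result
#'
#' Convenience constructor combining [stack_richness()], member
#' binarization and [pft_presence()] for one PFT on one scenario.
#'
#' @param pft PFT name.
#' @param ensembles list of [species_ensemble()] objects for the member
#'   species (expected 4).
#' @param min_agree learner-agreement threshold for species binarization.
#' @param presence_min bS-SDM threshold for PFT presence.
#' @return object of class `pft_result`: list with `pft`, `species`,
#'   `richness`, `bs_sdm`, `presence`.
#' @export
pft_result <- function(pft, ensembles, min_agree = 3, presence_min = 2) {
  binary <- lapply(ensembles, function(e)
    binarize_species(e$learner_maps, e$thresholds, min_agree = min_agree))
  pres <- pft_presence(binary, presence_min = presence_min)
  structure(list(pft = pft,
                 species = vapply(ensembles, `[[`, "", "species"),
                 richness = stack_richness(lapply(ensembles, `[[`, "overall_map")),
                 bs_sdm = pres$bs_sdm,
                 presence = pres$presence),
            class = "pft_result")
}
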