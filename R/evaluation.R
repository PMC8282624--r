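#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation: the probability that a randomly
#' chosen presence outscores a randomly chosen absence, with ties counted
#' one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical), same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Continuous Boyce Index
#'
#' Moving windows of width `window_frac` times the suitability range are
#' slid across the range at `n_windows` positions. In each window, P is the
#' fraction of presence suitabilities inside and E the fraction of
#' background suitabilities inside; windows with E = 0 are dropped, and the
#' index is the Spearman rank correlation between P/E and the window
#' midpoint. +1 means predicted suitability ranks habitat use perfectly.
#'
#' @param suit_presence suitability values at presence points, in `[0, 1]`.
#' @param suit_background suitability values at background points, in
#'   `[0, 1]`.
#' @param n_windows number of window positions.
#' @param window_frac window width as a fraction of the suitability range.
#' @return CBI in `[-1, 1]`.
#' @export
boyce_index <- function(suit_presence, suit_background,
                        n_windows = 101, window_frac = 0.1) {
  if (length(suit_background) == 0L) stop("background must be non-empty")
  if (length(suit_presence) == 0L) stop("presences must be non-empty")
  all_s <- c(suit_presence, suit_background)
  if (any(all_s < 0 | all_s > 1)) stop("suitabilities must lie in [0, 1]")
  rng <- range(all_s)
  width <- window_frac * diff(rng)
  if (width <= 0) stop("degenerate suitability range: fewer than 3 usable windows")
  lo <- seq(rng[1], rng[2] - width, length.out = n_windows)
  hi <- lo + width
  p <- vapply(seq_len(n_windows), function(i)
    mean(suit_presence >= lo[i] & suit_presence <= hi[i]), 0)
  e <- vapply(seq_len(n_windows), function(i)
    mean(suit_background >= lo[i] & suit_background <= hi[i]), 0)
  use <- e > 0
  if (sum(use) < 3L) stop("fewer than 3 usable windows: CBI undefined")
  stats::cor(p[use] / e[use], (lo + hi)[use] / 2, method = "spearman")
}

#' Calibration statistic summarizing the calibration plot
#'
#' Predicted probabilities are grouped into equal-width bins over `[0, 1]`;
#' the statistic is one minus the occupancy-weighted mean absolute gap
#' between mean predicted probability and observed presence frequency per
#' bin. 1 = perfectly calibrated, 0 = maximally miscalibrated. Optional
#' case weights make the statistic consistent with weighted model fits.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels binary outcomes, same length.
#' @param n_bins number of equal-width bins.
#' @param weights optional non-negative case weights.
#' @return statistic in `[0, 1]`.
#' @export
calibration_statistic <- function(probs, labels, n_bins = 10, weights = NULL) {
  labels <- as.numeric(labels)
  if (length(probs) == 0L) stop("empty input")
  stopifnot(length(probs) == length(labels))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(probs))
  bin <- pmin(pmax(ceiling(probs * n_bins), 1L), n_bins)
  total_w <- sum(weights)
  gap <- 0
  for (b in unique(bin)) {
    in_b <- bin == b
    w_b <- sum(weights[in_b]) / total_w
    pred_b <- stats::weighted.mean(probs[in_b], weights[in_b])
    obs_b <- stats::weighted.mean(labels[in_b], weights[in_b])
    gap <- gap + w_b * abs(pred_b - obs_b)
  }
  1 - gap
}

#' Filter learners by replicate-mean evaluation metrics
#'
#' A learner is retained only if every applicable metric (replicate-mean
#' AUC, CBI and calibration statistic) reaches the threshold. The
#' calibration statistic is waived for presence-only learners, which do not
#' produce absolute probabilities.
#'
#' @param metrics data.frame with columns `learner`, `auc`, `cbi`, `cal`
#'   (`cal` may be `NA` for presence-only learners).
#' @param threshold minimum value for every applicable metric.
#' @param presence_only character vector of learner names whose calibration
#'   statistic is not required.
#' @return character vector of retained learner names (possibly empty, with
#'   a warning).
#' @export
filter_models <- function(metrics, threshold = 0.7, presence_only = character()) {
  stopifnot(all(c("learner", "auc", "cbi", "cal") %in% names(metrics)))
  cal_ok <- metrics$learner %in% presence_only |
    (!is.na(metrics$cal) & metrics$cal >= threshold)
  keep <- metrics$auc >= threshold & metrics$cbi >= threshold & cal_ok
  retained <- metrics$learner[keep]
  if (length(retained) == 0L)
    warning("no learner passed the evaluation threshold of ", threshold)
  retained
}
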