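canonical_factors <- c("algorithm", "replicate", "rcp", "gcm")

#' ANOVA variance partition of projected probabilities
#'
#' Main-effects analysis of variance of one cell's (or species') projected
#' occurrence probabilities across the factors algorithm, replicate
#' (training dataset), RCP and GCM, fitted with [stats::aov()] in the
#' canonical factor order. Sequential sums of squares equal marginal sums
#' of squares on balanced designs; on unbalanced designs the sequential
#' decomposition in canonical order is reported. The residual absorbs all
#' interactions.
#'
#' @param values data.frame with a numeric `value` column and factor
#'   columns among `algorithm`, `replicate`, `rcp`, `gcm` (at least one
#'   with >= 2 levels).
#' @return object of class `variance_partition`: list with `fractions`
#'   (named over the four factors), `residual`, `n`, `degenerate`.
#' @export
anova_partition <- function(values) {
  stopifnot("value" %in% names(values))
  if (nrow(values) < 2L) stop("at least two observations are required")
  present <- intersect(canonical_factors, names(values))
  if (!length(present)) stop("no recognized factor columns")
  for (f in present) values[[f]] <- factor(values[[f]])
  active <- present[vapply(values[present], nlevels, 0L) >= 2L]
  fractions <- stats::setNames(rep(0, length(canonical_factors)),
                               canonical_factors)
  ss_total <- sum((values$value - mean(values$value))^2)
  if (ss_total < 1e-24)
    return(structure(list(fractions = fractions, residual = 0,
                          n = nrow(values), degenerate = TRUE),
                     class = "variance_partition"))
  if (!length(active)) stop("at least one factor needs two or more levels")
  form <- stats::as.formula(paste("value ~", paste(active, collapse = " + ")))
  fit <- stats::aov(form, data = values)
  ss <- summary(fit)[[1L]][["Sum Sq"]]
  terms <- rownames(summary(fit)[[1L]])
  terms <- trimws(terms)
  for (i in seq_along(active))
    fractions[active[i]] <- ss[match(active[i], terms)] / ss_total
  structure(list(fractions = fractions,
                 residual = 1 - sum(fractions),
                 n = nrow(values), degenerate = FALSE),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("<variance_partition>",
      if (x$degenerate) "(degenerate: zero variance)" else "", "\n")
  print(round(c(x$fractions, residual = x$residual), 4))
  invisible(x)
}

#' Rank uncertainty factors across cells
#'
#' @param partitions list of [anova_partition()] results.
#' @return data.frame with columns `factor`, `median_fraction`, ordered by
#'   decreasing median fraction (ties keep the canonical factor order).
#' @export
rank_factors <- function(partitions) {
  if (!length(partitions)) stop("at least one partition is required")
  m <- do.call(rbind, lapply(partitions, `[[`, "fractions"))
  med <- apply(m, 2L, stats::median)
  ord <- order(-med)  # order() is stable: ties keep canonical order
  data.frame(factor = canonical_factors[ord],
             median_fraction = unname(med[ord]), row.names = NULL)
}
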