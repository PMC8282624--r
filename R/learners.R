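#' Learner specifications for the SDM ensemble
#'
#' A learner is a pluggable presence/pseudo-absence classifier: `fit(x, y,
#' w)` must return a prediction function mapping a data.frame of predictor
#' values to occurrence probabilities in `[0, 1]`. Each learner also
#' carries its pseudo-absence strategy and count rule, which the ensemble
#' machinery resolves per species.
#'
#' Four reference learners are provided, mirroring the four model families
#' commonly retained in tropical-forest SDM ensembles:
#' * `learner_gam()` — binomial generalized additive model with thin-plate
#'   smooths (mgcv).
#' * `learner_spline()` — adaptive piecewise-linear classifier: lasso
#'   logistic regression on hinge basis functions (glmnet), which performs
#'   the knot selection adaptively through the L1 penalty.
#' * `learner_maxent()` — maximum-entropy-style presence/background model:
#'   ridge logistic density-ratio estimation on linear + quadratic
#'   features (glmnet). Flagged presence-only, so the calibration
#'   statistic is waived for it.
#' * `learner_rf()` — probability random forest (ranger).
#'
#' @param name unique learner name.
#' @param fit function `(x, y, w) -> function(newdata) -> probabilities`.
#' @param pa_strategy pseudo-absence strategy: `"random"`, `"disk"` or
#'   `"stratified"`.
#' @param pa_n pseudo-absence count: a number, or `"equal"` for one per
#'   presence.
#' @param presence_only logical; `TRUE` for density-ratio learners whose
#'   output is a relative (not absolute) probability.
#' @param disk_radii inner/outer radii (cells) of the disk strategy's
#'   annulus.
#' @param hyper named list of hyperparameters kept with the spec.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(name, fit, pa_strategy = "random", pa_n = 10000,
                         presence_only = FALSE, disk_radii = c(2, 20),
                         hyper = list()) {
  if (!pa_strategy %in% c("random", "disk", "stratified"))
    stop("unknown pseudo-absence strategy: ", pa_strategy)
  structure(list(name = name, fit = fit, pa_strategy = pa_strategy,
                 pa_n = pa_n, presence_only = presence_only,
                 disk_radii = disk_radii, hyper = hyper),
            class = "learner_spec")
}

#' @rdname learner_spec
#' @param k basis dimension per smooth term.
#' @export
learner_gam <- function(pa_n = 10000, k = 5) {
  fit <- function(x, y, w) {
    dat <- cbind(x, .y = y)
    terms <- vapply(names(x), function(v) {
      ku <- min(k, length(unique(x[[v]])) - 1L)
      if (ku >= 3) sprintf("s(%s, k = %d)", v, ku) else v
    }, "")
    form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    m <- suppressWarnings(
      mgcv::gam(form, family = stats::binomial(), data = dat, weights = w))
    vars <- names(x)
    structure(function(newdata) {
      p <- as.numeric(stats::predict(m, newdata = newdata, type = "response"))
      pmin(pmax(p, 0), 1)
    }, vars = vars)
  }
  learner_spec("GAM", fit, pa_strategy = "random", pa_n = pa_n,
               hyper = list(k = k))
}

# Hinge basis: for each variable, max(0, x - knot) and max(0, knot - x) at
# interior quantile knots of the training sample, plus the linear term.
hinge_basis <- function(x, knots) {
  cols <- list()
  for (v in names(knots)) {
    xv <- x[[v]]
    cols[[v]] <- xv
    for (i in seq_along(knots[[v]])) {
      kk <- knots[[v]][i]
      cols[[paste0(v, "_h", i)]] <- pmax(xv - kk, 0)
      cols[[paste0(v, "_g", i)]] <- pmax(kk - xv, 0)
    }
  }
  do.call(cbind, cols)
}

#' @rdname learner_spec
#' @param n_knots hinge knots per variable (at interior quantiles).
#' @export
learner_spline <- function(pa_n = 10000, n_knots = 8) {
  fit <- function(x, y, w) {
    knots <- lapply(x, function(v)
      unique(stats::quantile(v, probs = seq_len(n_knots) / (n_knots + 1),
                             names = FALSE)))
    xm <- hinge_basis(x, knots)
    cv <- glmnet::cv.glmnet(xm, y, family = "binomial", weights = w,
                            alpha = 1, nfolds = 4)
    vars <- names(x)
    structure(function(newdata) {
      p <- as.numeric(stats::predict(cv, newx = hinge_basis(newdata, knots),
                                     s = "lambda.min", type = "response"))
      pmin(pmax(p, 0), 1)
    }, vars = vars)
  }
  learner_spec("SPLINE", fit, pa_strategy = "random", pa_n = pa_n,
               hyper = list(n_knots = n_knots))
}

#' @rdname learner_spec
#' @export
learner_maxent <- function(pa_n = 10000) {
  quad_basis <- function(x) {
    xm <- as.matrix(x)
    cbind(xm, xm^2)
  }
  fit <- function(x, y, w) {
    cv <- glmnet::cv.glmnet(quad_basis(x), y, family = "binomial",
                            weights = w, alpha = 0, nfolds = 4)
    vars <- names(x)
    structure(function(newdata) {
      p <- as.numeric(stats::predict(cv, newx = quad_basis(newdata),
                                     s = "lambda.min", type = "response"))
      pmin(pmax(p, 0), 1)
    }, vars = vars)
  }
  learner_spec("MAXENT", fit, pa_strategy = "random", pa_n = pa_n,
               presence_only = TRUE)
}

#' @rdname learner_spec
#' @param num_trees trees per forest.
#' @export
learner_rf <- function(pa_n = "equal", num_trees = 300) {
  fit <- function(x, y, w) {
    m <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        probability = TRUE, num.trees = num_trees,
                        case.weights = w, num.threads = 1,
                        seed = sample.int(.Machine$integer.max, 1))
    vars <- names(x)
    structure(function(newdata) {
      p <- stats::predict(m, data = newdata, num.threads = 1)$predictions[, "1"]
      pmin(pmax(as.numeric(p), 0), 1)
    }, vars = vars)
  }
  learner_spec("RF", fit, pa_strategy = "disk", pa_n = pa_n,
               hyper = list(num_trees = num_trees))
}

#' Default four-learner roster
#'
#' @param pa_n_background background/pseudo-absence count for the
#'   regression-type and maximum-entropy-style learners.
#' @return named list of [learner_spec()] objects.
#' @export
default_learners <- function(pa_n_background = 10000) {
  specs <- list(learner_gam(pa_n = pa_n_background),
                learner_spline(pa_n = pa_n_background),
                learner_maxent(pa_n = pa_n_background),
                learner_rf())
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}
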