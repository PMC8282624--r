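# Independent brute-force oracles and small fixture builders shared across
# the test files. Each oracle is written directly from the defining
# formula, structured differently from the package implementation.

# AUC as an explicit O(n^2) concordant/discordant pair count, ties = 1/2.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# maxSSS by a literal exhaustive scan in exact rational arithmetic:
# sens + spec = (tp*n0 + tn*n1)/(n1*n0), so integer numerators compare
# mathematically tied objectives exactly; first (smallest) maximum kept.
oracle_max_sss <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  best_tau <- NA_real_
  best_num <- -Inf
  for (tau in sort(unique(scores))) {
    tp <- sum(scores[labels == 1] >= tau)
    tn <- sum(scores[labels == 0] < tau)
    if (tp * n0 + tn * n1 > best_num) {
      best_num <- tp * n0 + tn * n1
      best_tau <- tau
    }
  }
  list(tau = best_tau, objective = best_num / (n1 * n0))
}

# VIF of one column by direct regression: 1 / (1 - R^2) from lm().
oracle_vif_lm <- function(df, j) {
  others <- setdiff(names(df), j)
  fit <- stats::lm(stats::reformulate(others, response = j), data = df)
  1 / (1 - summary(fit)$r.squared)
}

# Pf, Pff and the fragmentation class of the focal cell of a full 3x3
# binary map, written directly from the class definitions: Pf = proportion
# of the nine cells covered; Pff = 2FF / (2FF + FN) over the 12 cardinally
# adjacent unordered pairs; classes by the quoted inequality rules.
oracle_frag_3x3 <- function(m) {
  stopifnot(identical(dim(m), c(3L, 3L)), m[2, 2] == 1)
  pf <- sum(m) / 9
  pairs <- rbind(
    cbind(1, 1, 1, 2), cbind(1, 2, 1, 3), cbind(2, 1, 2, 2),
    cbind(2, 2, 2, 3), cbind(3, 1, 3, 2), cbind(3, 2, 3, 3),
    cbind(1, 1, 2, 1), cbind(2, 1, 3, 1), cbind(1, 2, 2, 2),
    cbind(2, 2, 3, 2), cbind(1, 3, 2, 3), cbind(2, 3, 3, 3))
  ff <- 0
  fn <- 0
  for (k in seq_len(nrow(pairs))) {
    a <- m[pairs[k, 1], pairs[k, 2]]
    b <- m[pairs[k, 3], pairs[k, 4]]
    if (a == 1 && b == 1) ff <- ff + 1
    if (a + b == 1) fn <- fn + 1
  }
  pff <- if (2 * ff + fn == 0) NA_real_ else 2 * ff / (2 * ff + fn)
  cls <- if (pf == 1) "interior"
  else if (pf < 0.4) "patch"
  else if (pf <= 0.6) "transitional"
  else if (pf - pff > 0) "perforated"
  else "edge"
  list(pf = pf, pff = pff, class = cls)
}

# Sequential main-effect sums of squares on a balanced design via group
# means, computed directly (balanced => sequential equals marginal SS).
oracle_balanced_ss <- function(df, factor_name) {
  gm <- mean(df$value)
  means <- tapply(df$value, df[[factor_name]], mean)
  counts <- tapply(df$value, df[[factor_name]], length)
  sum(counts * (means - gm)^2)
}

# Tiny environment stack with hand-set layers for unit tests.
make_tiny_env <- function(n_rows = 5, n_cols = 5, temperature = 20,
                          precipitation = 1500, elevation = 0) {
  g <- grid_spec(n_rows, n_cols, lat_min = 0, lat_max = n_rows,
                 lon_min = 0, lon_max = n_cols)
  as_layer <- function(x) {
    if (is.matrix(x)) x else matrix(x, n_rows, n_cols)
  }
  env_stack(g, list(temperature = as_layer(temperature),
                    precipitation = as_layer(precipitation),
                    elevation = as_layer(elevation)))
}

# Cheap pluggable learner (plain logistic regression) for fast unit tests
# of the replicate machinery; the pipeline-grade learners are exercised in
# the acceptance suite.
learner_glm_test <- function(pa_n = 200) {
  fit <- function(x, y, w) {
    dat <- cbind(x, .y = y)
    m <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                     data = dat, weights = w))
    structure(function(newdata) {
      p <- stats::predict(m, newdata = newdata, type = "response")
      pmin(pmax(as.numeric(p), 0), 1)
    }, vars = names(x))
  }
  learner_spec("GLMTEST", fit, pa_strategy = "random", pa_n = pa_n)
}

# Enumerate all 512 3x3 binary configurations with the focal cell present.
all_focal_configs <- function() {
  lapply(0:511, function(k) {
    m <- matrix(as.integer(intToBits(k))[1:9], 3, 3)
    m[2, 2] <- 1L
    m
  })
}
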