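balanced_design <- function(n_alg = 4, n_rep = 10, n_rcp = 3, n_gcm = 3) {
  expand.grid(algorithm = paste0("alg", seq_len(n_alg)),
              replicate = seq_len(n_rep),
              rcp = paste0("rcp", seq_len(n_rcp)),
              gcm = paste0("gcm", seq_len(n_gcm)))
}

# Level effects rescaled to an exact empirical variance, so the injected
# variance ratios are known rather than estimated.
exact_effects <- function(n_levels, variance) {
  e <- seq_len(n_levels) - mean(seq_len(n_levels))
  e * sqrt(variance / mean(e^2))
}

test_that("single-factor and degenerate designs partition as expected", {
  d <- balanced_design()
  d$value <- as.numeric(d$algorithm)
  p <- anova_partition(d)
  expect_equal(unname(p$fractions["algorithm"]), 1, tolerance = 1e-9)
  expect_equal(sum(p$fractions) + p$residual, 1, tolerance = 1e-9)
  expect_true(all(p$fractions[c("replicate", "rcp", "gcm")] < 1e-9))

  d$value <- 0.42
  pd <- anova_partition(d)
  expect_true(pd$degenerate)
  expect_true(all(pd$fractions == 0))

  expect_error(anova_partition(data.frame(algorithm = "a", value = 1)),
               "at least two")
})

test_that("injected variance ratios are recovered on a balanced 4x10x3x3 design", {
  d <- balanced_design(4, 10, 3, 3)
  inj <- c(algorithm = 4, replicate = 0.5, rcp = 2, gcm = 1)
  eff <- list(algorithm = exact_effects(4, inj["algorithm"]),
              replicate = exact_effects(10, inj["replicate"]),
              rcp = exact_effects(3, inj["rcp"]),
              gcm = exact_effects(3, inj["gcm"]))
  set.seed(91)
  noise_sd <- 0.05
  d$value <- eff$algorithm[as.integer(d$algorithm)] +
    eff$replicate[d$replicate] +
    eff$rcp[as.integer(d$rcp)] +
    eff$gcm[as.integer(d$gcm)] +
    rnorm(nrow(d), sd = noise_sd)
  p <- anova_partition(d)
  expect_equal(sum(p$fractions) + p$residual, 1, tolerance = 1e-9)
  want <- inj / (sum(inj) + noise_sd^2)
  for (f in names(inj))
    expect_lt(abs(p$fractions[[f]] - want[[f]]) / want[[f]], 0.10)

  # sums of squares against the brute-force group-mean oracle
  ss_total <- sum((d$value - mean(d$value))^2)
  for (f in names(inj))
    expect_equal(p$fractions[[f]] * ss_total, oracle_balanced_ss(d, f),
                 tolerance = 1e-8)
})

test_that("partitions ignore level labels and factor entry order on balanced designs", {
  d <- balanced_design(3, 4, 2, 2)
  set.seed(92)
  d$value <- rnorm(nrow(d))
  p1 <- anova_partition(d)

  relab <- d
  relab$algorithm <- factor(relab$algorithm,
                            labels = c("zz", "aa", "mm"))
  p2 <- anova_partition(relab)
  expect_equal(p1$fractions, p2$fractions, tolerance = 1e-10)

  reord <- d[, c("gcm", "rcp", "replicate", "algorithm", "value")]
  p3 <- anova_partition(reord)
  expect_equal(p1$fractions, p3$fractions, tolerance = 1e-10)
})

test_that("factor ranking orders by median fraction with canonical tie order", {
  mk <- function(fr) structure(list(fractions = fr, residual = 1 - sum(fr),
                                    n = 10, degenerate = FALSE),
                               class = "variance_partition")
  fr1 <- c(algorithm = 0.6, replicate = 0.05, rcp = 0.2, gcm = 0.1)
  r1 <- rank_factors(list(mk(fr1)))
  expect_identical(r1$factor, c("algorithm", "rcp", "gcm", "replicate"))

  # algorithm-dominant ensemble of partitions -> algorithm ranked first
  set.seed(93)
  parts <- lapply(1:20, function(i) {
    f <- c(algorithm = runif(1, 0.5, 0.7), replicate = runif(1, 0, 0.05),
           rcp = runif(1, 0.1, 0.2), gcm = runif(1, 0.05, 0.1))
    mk(f)
  })
  expect_identical(rank_factors(parts)$factor[1], "algorithm")

  tied <- mk(c(algorithm = 0.25, replicate = 0.25, rcp = 0.25, gcm = 0.25))
  expect_identical(rank_factors(list(tied))$factor,
                   c("algorithm", "replicate", "rcp", "gcm"))
})
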