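test_that("thinning keeps one record per species per cell and is idempotent", {
  g <- grid_spec(4, 4, 0, 4, 0, 4)
  occ <- occurrence_set(c("a", "a", "a", "b"),
                        lon = c(0.2, 0.4, 2.5, 0.3),
                        lat = c(3.8, 3.6, 1.5, 3.9))
  out <- thin_to_grid(occ, g)
  expect_identical(nrow(out), 3L)           # a's two co-cell records collapse
  expect_equal(out$lon[1], 0.2)             # first in input order kept
  expect_identical(thin_to_grid(out, g), out)

  # all distinct cells -> unchanged
  occ2 <- occurrence_set(rep("a", 3), lon = c(0.5, 1.5, 2.5), lat = rep(0.5, 3))
  expect_equal(nrow(thin_to_grid(occ2, g)), 3L)

  # single-cell grid -> single record
  g1 <- grid_spec(1, 1, 0, 1, 0, 1)
  occ3 <- occurrence_set(rep("a", 100), lon = runif(100), lat = runif(100))
  expect_identical(nrow(thin_to_grid(occ3, g1)), 1L)

  # out-of-extent and off-land records are dropped with a message
  occ4 <- occurrence_set(c("a", "a"), lon = c(0.5, 9), lat = c(0.5, 0.5))
  expect_message(out4 <- thin_to_grid(occ4, g), "dropped")
  expect_identical(nrow(out4), 1L)
  land <- matrix(TRUE, 4, 4); land[4, 1] <- FALSE
  expect_message(out5 <- thin_to_grid(occ4, g, land_mask = land), "2 record")
  expect_identical(nrow(out5), 0L)

  expect_identical(nrow(thin_to_grid(occ4[0, ], g)), 0L)
})

test_that("minimum-record screening flags species at the boundary", {
  occ <- occurrence_set(c(rep("pinus", 206), rep("rare", 199)),
                        lon = runif(405), lat = runif(405))
  rep_tab <- check_min_records(occ, minimum = 200)
  expect_true(rep_tab$pass[rep_tab$species == "pinus"])
  expect_false(rep_tab$pass[rep_tab$species == "rare"])
  empty <- check_min_records(occ[0, ], species = c("x", "y"))
  expect_false(any(empty$pass))
})

test_that("stepwise VIF matches the direct-regression oracle and removes collinear variables", {
  set.seed(7)
  n <- 1000
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  res <- vif_stepwise(df, threshold = 10)
  expect_identical(nrow(res$steps), 0L)
  expect_setequal(res$retained, names(df))
  expect_true(all(abs(res$vif_retained - 1) < 0.05))

  # per-step VIFs equal the brute-force 1/(1 - R^2) oracle
  df$x5 <- df$x1 + df$x2 + rnorm(n, sd = 0.1)
  for (j in names(df))
    expect_equal(unname(vif_stepwise(df, threshold = Inf)$vif_retained[j]),
                 oracle_vif_lm(df, j), tolerance = 1e-8)
  res2 <- vif_stepwise(df, threshold = 10)
  expect_identical(res2$steps$variable, "x5")
  expect_setequal(res2$retained, c("x1", "x2", "x3", "x4"))
  # terminal state verified by direct recomputation
  for (j in res2$retained)
    expect_lt(oracle_vif_lm(df[res2$retained], j), 10)

  # duplicated column: exactly one of the pair removed (the later one)
  df2 <- data.frame(a = rnorm(200), b = rnorm(200))
  df2$a_copy <- df2$a
  res3 <- vif_stepwise(df2)
  expect_identical(res3$steps$variable[1], "a_copy")
  expect_setequal(res3$retained, c("a", "b"))

  # constant column removed first with a warning
  df3 <- data.frame(a = rnorm(50), b = rnorm(50), c = rep(1, 50))
  expect_warning(res4 <- vif_stepwise(df3), "constant")
  expect_identical(res4$steps$variable[1], "c")
})

test_that("clamping is a projection onto the training range with novelty flags", {
  g <- grid_spec(4, 4, 0, 4, 0, 4)
  env <- make_tiny_env(4, 4, temperature = matrix(seq(10, 25, length.out = 16), 4, 4),
                       precipitation = 1000)
  ranges <- training_ranges(env)

  within <- clamp_to_range(env, ranges)
  expect_equal(within$env$layers, env$layers)
  expect_true(all(!unlist(within$novelty)))

  warmer <- apply_climate_delta(env, climate_delta("w", offset = c(temperature = 3)))
  cl <- clamp_to_range(warmer, ranges)
  tmax <- ranges$max[ranges$layer == "temperature"]
  expect_true(all(cl$env$layers$temperature <= tmax))
  expect_identical(cl$novelty$temperature,
                   warmer$layers$temperature > tmax)
  # single exceeding value
  one <- env
  one$layers$temperature[2, 2] <- 99
  cl1 <- clamp_to_range(one, ranges)
  expect_equal(cl1$env$layers$temperature[2, 2], tmax)
  expect_identical(sum(cl1$novelty$temperature), 1L)

  # entire layer above the range -> novelty fraction 1
  shift_all <- apply_climate_delta(env, climate_delta("s", offset = c(temperature = 100)))
  expect_equal(unname(clamp_to_range(shift_all, ranges)$novel_fraction["temperature"]), 1)

  # projection: clamp(clamp(x)) = clamp(x)
  twice <- clamp_to_range(cl$env, ranges)
  expect_equal(twice$env$layers, cl$env$layers)
  rr <- training_ranges(cl$env)
  expect_true(all(rr$min >= ranges$min - 1e-12 & rr$max <= ranges$max + 1e-12))

  expect_error(clamp_to_range(env, ranges[ranges$layer != "temperature", ]),
               "temperature")
})
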