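test_that("landscape generation is deterministic and honours the lapse rate", {
  g <- grid_spec(30, 25, 4, 24, -100, -80)
  e1 <- generate_landscape(g, seed = 11)
  e2 <- generate_landscape(g, seed = 11)
  expect_identical(e1$layers, e2$layers)
  e3 <- generate_landscape(g, seed = 12)
  expect_false(identical(e1$layers$elevation, e3$layers$elevation))

  expect_true(all(e1$layers$elevation >= 0))
  expect_identical(dim(e1$layers$slope), c(30L, 25L))

  # lapse: two cells sharing the sea-level temperature differ by
  # -lapse_rate * (elevation difference)
  p <- landscape_params(t_noise = 0, elev_range = 1000, ridge_height = 0,
                        precip_noise = 0, seasonality_noise = 0)
  e <- generate_landscape(g, p, seed = 5)
  dT <- e$layers$temperature - (p$t_sealevel - p$lapse_rate * e$layers$elevation)
  expect_lt(max(abs(dT)), 1e-9)
  i <- which.max(e$layers$elevation)
  j <- which.min(e$layers$elevation)
  expect_equal(e$layers$temperature[i] - e$layers$temperature[j],
               -p$lapse_rate * (e$layers$elevation[i] - e$layers$elevation[j]))

  expect_error(generate_landscape(g, landscape_params(lapse_rate = -1)),
               "lapse_rate")
  expect_error(grid_spec(0, 5, 0, 1, 0, 1), "positive")
})

test_that("zero noise amplitudes and flat terrain give spatially constant layers", {
  g <- grid_spec(8, 8, 0, 8, 0, 8)
  p <- landscape_params(elev_range = 0, ridge_height = 0, t_noise = 0,
                        precip_noise = 0, precip_north = 1000,
                        precip_south = 1000, seasonality_noise = 0,
                        soil_noise = 0)
  e <- generate_landscape(g, p, seed = 3)
  for (nm in names(e$layers))
    expect_lt(diff(range(e$layers[[nm]])), 1e-9)
})

test_that("true suitability is the product of Gaussian responses", {
  set.seed(42)
  temp <- matrix(runif(25, 10, 30), 5, 5)
  prec <- matrix(runif(25, 500, 3000), 5, 5)
  env <- make_tiny_env(5, 5, temperature = temp, precipitation = prec)
  niche <- niche_spec("sp", c(temperature = 22, precipitation = 2000),
                      c(temperature = 3, precipitation = 400), prob_max = 0.8)
  suit <- true_suitability(env, niche)
  # cell-by-cell brute force
  for (i in 1:5) for (j in 1:5) {
    expected <- 0.8 *
      exp(-(temp[i, j] - 22)^2 / (2 * 3^2)) *
      exp(-(prec[i, j] - 2000)^2 / (2 * 400^2))
    expect_equal(suit[i, j], expected, tolerance = 1e-12)
  }
  # at-optimum value and symmetry around the optimum
  env_opt <- make_tiny_env(1, 1, temperature = 22, precipitation = 2000)
  expect_equal(true_suitability(env_opt, niche)[1, 1], 0.8)
  n1 <- niche_spec("s1", c(temperature = 22), c(temperature = 3))
  up <- true_suitability(make_tiny_env(1, 1, temperature = 22 + 1.7), n1)
  dn <- true_suitability(make_tiny_env(1, 1, temperature = 22 - 1.7), n1)
  expect_equal(up[1, 1], dn[1, 1])

  expect_error(true_suitability(env, niche_spec("x", c(ph = 7), c(ph = 1))),
               "ph")
})

test_that("occurrence sampling follows suitability and is reproducible", {
  g <- grid_spec(10, 10, 0, 10, 0, 10)
  set.seed(9)
  temp <- matrix(runif(100, 10, 30), 10, 10)
  env <- make_tiny_env(10, 10, temperature = temp)
  niche <- niche_spec("sp", c(temperature = 20), c(temperature = 4))

  o1 <- sample_occurrences(env, niche, 500, seed = 4)
  o2 <- sample_occurrences(env, niche, 500, seed = 4)
  expect_identical(o1, o2)
  expect_identical(nrow(o1), 500L)
  expect_true(all(o1$lon >= 0 & o1$lon <= 10 & o1$lat >= 0 & o1$lat <= 10))

  # suitability concentrated in one cell -> every record lands there
  suit1 <- matrix(0, 10, 10)
  suit1[3, 7] <- 25  # temperature optimum only at this cell
  env1 <- make_tiny_env(10, 10, temperature = suit1)
  niche1 <- niche_spec("sp", c(temperature = 25), c(temperature = 0.1))
  oo <- sample_occurrences(env1, niche1, 50, seed = 1)
  idx <- cell_index(g, oo$lon, oo$lat)
  expect_true(all(idx$row == 3 & idx$col == 7))

  # large-n: per-cell counts track true suitability
  big <- sample_occurrences(env, niche, 10000, seed = 8)
  idx <- cell_index(g, big$lon, big$lat)
  counts <- table(factor(paste(idx$row, idx$col), levels = paste(
    rep(1:10, 10), rep(1:10, each = 10))))
  suit <- as.vector(true_suitability(env, niche))
  expect_gt(cor(as.numeric(counts), suit, method = "spearman"), 0.9)

  expect_error(sample_occurrences(env1,
    niche_spec("z", c(temperature = 300), c(temperature = 1e-6)), 10),
    "zero")
})

test_that("empirical sampling frequencies match normalized suitability x bias", {
  g <- grid_spec(10, 10, 0, 10, 0, 10)
  set.seed(21)
  temp <- matrix(runif(100, 15, 25), 10, 10)
  env <- make_tiny_env(10, 10, temperature = temp)
  niche <- niche_spec("sp", c(temperature = 20), c(temperature = 3))
  bias <- matrix(runif(100, 0.2, 1), 10, 10)
  occ <- sample_occurrences(env, niche, 1e5, bias = bias, seed = 13)
  idx <- cell_index(g, occ$lon, occ$lat)
  cell <- (idx$col - 1L) * 10L + idx$row
  counts <- tabulate(cell, nbins = 100)
  p <- as.vector(true_suitability(env, niche) * bias)
  p <- p / sum(p)
  gof <- suppressWarnings(chisq.test(counts, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("climate deltas transform climate layers only and never mutate input", {
  g <- grid_spec(6, 6, 0, 6, 0, 6)
  env <- generate_landscape(g, landscape_params(corr_length = 2), seed = 2)
  orig <- env$layers

  id <- climate_delta("identity", offset = c(temperature = 0),
                      factor = c(precipitation = 1))
  expect_equal(apply_climate_delta(env, id)$layers, orig)

  d <- climate_delta("warm-dry", offset = c(temperature = 2),
                     factor = c(precipitation = 0.8))
  out <- apply_climate_delta(env, d)
  expect_equal(out$layers$temperature, orig$temperature + 2)
  expect_equal(sum(out$layers$precipitation), 0.8 * sum(orig$precipitation))
  # conservation: non-climate layers bitwise unchanged, input untouched
  for (nm in c("elevation", "slope", "soil_sand", "soil_clay", "soil_ph"))
    expect_identical(out$layers[[nm]], orig[[nm]])
  expect_identical(env$layers, orig)

  expect_error(apply_climate_delta(env,
    climate_delta("bad", offset = c(elevation = 100))), "non-climate")
  expect_error(climate_delta("bad", factor = c(precipitation = -1)), "> 0")
})
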