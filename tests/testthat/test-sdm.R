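make_sdm_fixture <- function(seed = 17, n_rows = 25, n_cols = 25, n_occ = 150) {
  g <- grid_spec(n_rows, n_cols, 4, 24, -100, -80)
  env <- generate_landscape(g, landscape_params(corr_length = 4), seed = seed)
  niche <- niche_spec("sp", c(temperature = 24, precipitation = 2200),
                      c(temperature = 4, precipitation = 600), 0.9)
  occ <- thin_to_grid(sample_occurrences(env, niche, n_occ, seed = seed + 1), g)
  list(g = g, env = env, niche = niche, occ = occ)
}

test_that("pseudo-absence strategies respect presences, counts and seeds", {
  fx <- make_sdm_fixture()
  spec_rand <- learner_spec("L", function(x, y, w) NULL, pa_n = 1000)
  pa <- draw_pseudo_absences(fx$env, fx$occ, spec_rand, seed = 5)
  expect_identical(nrow(pa), 1000L)
  idx <- cell_index(fx$g, fx$occ$lon, fx$occ$lat)
  pres_cells <- unique(paste(idx$row, idx$col))
  expect_false(any(paste(pa$row, pa$col) %in% pres_cells))
  expect_identical(draw_pseudo_absences(fx$env, fx$occ, spec_rand, seed = 5), pa)

  spec_disk <- learner_spec("D", function(x, y, w) NULL, pa_strategy = "disk",
                            pa_n = "equal", disk_radii = c(2, 15))
  pd <- draw_pseudo_absences(fx$env, fx$occ, spec_disk, seed = 6)
  expect_identical(nrow(pd), nrow(fx$occ))
  dmin <- sapply(seq_len(nrow(pd)), function(k)
    min(sqrt((pd$row[k] - idx$row)^2 + (pd$col[k] - idx$col)^2)))
  expect_true(all(dmin >= 2 & dmin <= 15))
  spec_empty <- learner_spec("D2", function(x, y, w) NULL,
                             pa_strategy = "disk", pa_n = 10,
                             disk_radii = c(500, 600))
  expect_error(draw_pseudo_absences(fx$env, fx$occ, spec_empty), "annulus")

  spec_strat <- learner_spec("S", function(x, y, w) NULL,
                             pa_strategy = "stratified", pa_n = 200)
  ps <- draw_pseudo_absences(fx$env, fx$occ, spec_strat, seed = 7)
  expect_identical(nrow(ps), 200L)
  expect_false(any(paste(ps$row, ps$col) %in% pres_cells))
})

test_that("replicate fitting keeps disjoint splits and near-perfect AUC on separable data", {
  fx <- make_sdm_fixture()
  lr <- learner_glm_test(pa_n = 300)
  pa <- draw_pseudo_absences(fx$env, fx$occ, lr, seed = 2)
  fits <- fit_replicates(lr, fx$occ, pa, fx$env, n_replicates = 12, seed = 3,
                         vars = c("temperature", "precipitation"))
  expect_length(fits, 12)
  for (f in fits) {
    expect_length(intersect(f$train, f$holdout), 0)
    n <- nrow(fx$occ) + nrow(pa)
    expect_identical(sort(c(f$train, f$holdout)), seq_len(n))
    # 70/30 split within each class, to the nearest row
    expect_equal(sum(f$train <= nrow(fx$occ)), round(0.7 * nrow(fx$occ)))
  }
  m <- replicate_metrics(fits)
  expect_identical(nrow(m), 12L)
  expect_true(all(m$auc >= 0 & m$auc <= 1))

  # perfectly separable virtual species: niche and background disjoint
  g <- grid_spec(20, 20, 0, 20, 0, 20)
  temp <- matrix(10, 20, 20); temp[1:10, ] <- 25
  env <- make_tiny_env(20, 20, temperature = temp)
  niche <- niche_spec("sep", c(temperature = 25), c(temperature = 0.5))
  # enough records that every suitable cell is occupied, so the background
  # cannot contain niche-identical cells
  occ <- thin_to_grid(sample_occurrences(env, niche, 3000, seed = 4), g)
  pa2 <- draw_pseudo_absences(env, occ, lr, seed = 5)
  fits2 <- fit_replicates(lr, occ, pa2, env, n_replicates = 10, seed = 6,
                          vars = "temperature")
  expect_gt(mean(replicate_metrics(fits2)$auc), 0.95)

  expect_error(fit_replicates(lr, fx$occ[1:5, ], pa, fx$env), "10 presences")
})

test_that("prediction maps are bounded, consistent and co-registered", {
  fx <- make_sdm_fixture()
  lr <- learner_glm_test(pa_n = 300)
  pa <- draw_pseudo_absences(fx$env, fx$occ, lr, seed = 2)
  fits <- fit_replicates(lr, fx$occ, pa, fx$env, n_replicates = 3, seed = 3,
                         vars = c("temperature", "precipitation"))
  map <- predict_map(fits[[1]], fx$env)
  expect_identical(dim(map), c(25L, 25L))
  expect_true(all(map >= 0 & map <= 1, na.rm = TRUE))

  # in-sample consistency: map values at training cells equal direct predictions
  idx <- cell_index(fx$g, fx$occ$lon, fx$occ$lat)
  direct <- fits[[1]]$model(env_values(fx$env, idx$row, idx$col,
                                       c("temperature", "precipitation")))
  expect_equal(map[cbind(idx$row, idx$col)], direct, tolerance = 1e-12)

  # constant environment -> constant map
  flat <- make_tiny_env(5, 5, temperature = 20, precipitation = 1500)
  mflat <- predict_map(fits[[1]], flat)
  expect_lt(diff(range(mflat)), 1e-12)

  bad_env <- make_tiny_env(5, 5)
  fits[[1]]$vars <- c("temperature", "npp")
  expect_error(predict_map(fits[[1]], bad_env), "npp")
})

test_that("ensemble means are exact, order-invariant and bounded", {
  set.seed(51)
  maps <- replicate(7, matrix(runif(30), 5, 6), simplify = FALSE)
  got <- ensemble_mean(maps)
  want <- Reduce(`+`, maps) / 7
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(ensemble_mean(rev(maps)), got, tolerance = 1e-12)
  expect_equal(ensemble_mean(maps[c(1, 1)]), maps[[1]])
  expect_equal(ensemble_mean(list(matrix(0, 2, 2), matrix(1, 2, 2))),
               matrix(0.5, 2, 2))
  lo <- Reduce(pmin, maps); hi <- Reduce(pmax, maps)
  expect_true(all(got >= lo - 1e-12 & got <= hi + 1e-12))
  expect_error(ensemble_mean(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "co-registered")
})

test_that("projection replicate subsetting is per learner, exact and seeded", {
  fake_fit <- function(learner, rep)
    structure(list(learner = learner, replicate = rep),
              class = "replicate_fit")
  fits <- c(lapply(1:20, fake_fit, learner = "A"),
            lapply(1:20, fake_fit, learner = "B"))
  sel <- select_projection_replicates(fits, k = 10, seed = 9)
  tab <- table(vapply(sel, `[[`, "", "learner"))
  expect_true(all(tab == 10))
  expect_identical(select_projection_replicates(fits, k = 10, seed = 9), sel)
  all20 <- select_projection_replicates(fits, k = 20, seed = 1)
  expect_identical(length(all20), 40L)
  expect_error(select_projection_replicates(fits, k = 21), "exceeds")
})
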