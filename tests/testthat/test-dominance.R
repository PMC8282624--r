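# Build a pft_result directly from matrices (bypassing the modelling chain)
fake_pft <- function(pft, richness, bs) {
  structure(list(pft = pft, species = paste0(pft, "_sp", 1:4),
                 richness = richness, bs_sdm = bs,
                 presence = !is.na(bs) & bs >= 2),
            class = "pft_result")
}

test_that("dominant PFT is the highest-richness qualifying type, else None", {
  r_hi <- matrix(2.4, 3, 3)
  r_lo <- matrix(2.39, 3, 3)
  bs3 <- matrix(3, 3, 3)
  bs1 <- matrix(1, 3, 3)

  # one PFT qualifies (bS-SDM = 3), the other does not (bS-SDM <= 1)
  dom <- dominant_pft(list(fake_pft("wet", r_hi, bs3),
                           fake_pft("dry", r_lo, bs1)))
  expect_true(all(dom$labels == "wet"))

  # nobody qualifies -> None
  dom_none <- dominant_pft(list(fake_pft("wet", r_hi, bs1),
                                fake_pft("dry", r_lo, bs1)))
  expect_true(all(dom_none$labels == "None"))

  # strict argmax between two qualifying candidates: 2.4 beats 2.39
  dom2 <- dominant_pft(list(fake_pft("wet", r_lo, bs3),
                            fake_pft("dry", r_hi, bs3)))
  expect_true(all(dom2$labels == "dry"))
  expect_true(all(!dom2$ties))

  # exact ties: canonical order wins and the tie is flagged
  dom3 <- dominant_pft(list(fake_pft("wet", r_hi, bs3),
                            fake_pft("dry", r_hi, bs3)))
  expect_true(all(dom3$labels == "wet"))
  expect_true(all(dom3$ties))

  # scale-free: multiplying all richness maps by a constant changes nothing
  dom4 <- dominant_pft(list(fake_pft("wet", r_lo * 1.3, bs3),
                            fake_pft("dry", r_hi * 1.3, bs3)))
  expect_identical(dom4$labels, dom2$labels)

  expect_error(dominant_pft(list()), "at least one")
})

test_that("area fractions sum to one and match direct tabulation", {
  set.seed(61)
  labels <- matrix(sample(c("a", "b", "None"), 100, replace = TRUE), 10, 10)
  dom <- structure(list(labels = labels, classes = c("a", "b", "None"),
                        ties = matrix(FALSE, 10, 10), grid_dim = c(10L, 10L)),
                   class = "dominance_map")
  af <- area_fractions(dom)
  expect_equal(sum(af$fraction), 1, tolerance = 1e-9)
  for (cl in dom$classes)
    expect_equal(af$area_km2[af$class == cl], sum(labels == cl))

  uni <- dom; uni$labels[] <- "a"
  afu <- area_fractions(uni)
  expect_equal(afu$fraction[afu$class == "a"], 1)

  # spherical weighting: equal-count classes at different latitudes differ in area
  g <- grid_spec(10, 10, 0, 60, 0, 10)
  areas <- cell_area_km2(g)
  north <- dom; north$labels[] <- "b"; north$labels[1:5, ] <- "a"
  af2 <- area_fractions(north, areas)
  expect_lt(af2$area_km2[af2$class == "a"], af2$area_km2[af2$class == "b"])
})

test_that("transition flows conserve class areas between the two dates", {
  set.seed(62)
  mk <- function() {
    labels <- matrix(sample(c("a", "b", "None"), 64, replace = TRUE), 8, 8)
    structure(list(labels = labels, classes = c("a", "b", "None"),
                   ties = matrix(FALSE, 8, 8), grid_dim = c(8L, 8L)),
              class = "dominance_map")
  }
  d1 <- mk(); d2 <- mk()
  fl <- transition_flows(d1, d2)
  expect_equal(sum(fl), 64)
  # row sums = present-day class areas; column sums = future class areas
  expect_equal(unname(rowSums(fl)),
               unname(sapply(d1$classes, function(cl) sum(d1$labels == cl))))
  expect_equal(unname(colSums(fl)),
               unname(sapply(d2$classes, function(cl) sum(d2$labels == cl))))
  # identical maps -> diagonal matrix
  fd <- transition_flows(d1, d1)
  expect_true(all(fd[upper.tri(fd)] == 0) && all(fd[lower.tri(fd)] == 0))
  # pairwise tabulation oracle
  for (i in d1$classes) for (j in d2$classes)
    expect_equal(fl[i, j], sum(d1$labels == i & d2$labels == j))
  d3 <- mk(); d3$grid_dim <- c(9L, 9L)
  expect_error(transition_flows(d1, d3), "different grids")
})
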