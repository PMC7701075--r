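# Weighted-distribution machinery: ingestion, weighting conversions,
# length <-> s mapping, quantile summaries.

test_that("length-table ingestion filters, counts and weights correctly", {
  d <- suppressMessages(ingest_length_table(c(40, 100, 100, 300)))
  expect_equal(d$metadata$n_removed, 1)
  expect_equal(d$grid, c(100, 300))
  # point masses (density x trapezoid node weights) are 2/3 and 1/3
  masses <- d$density * diff(c(0, cumsum(c(100, 100))))
  expect_equal(unname(masses), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_error(suppressMessages(ingest_length_table(c(10, 20, 49))),
               "minimum-length filter")
})

test_that("ingested synthetic lognormal sample recovers the generator mean", {
  x <- generate_afm_fixture(n = 2000, seed = 7)
  d <- suppressMessages(ingest_length_table(x$length_nm))
  expect_equal(summary(d)$mean, 395, tolerance = 0.05)
})

test_that("number -> mass conversion weights by length at constant height", {
  d <- weighted_distribution(c(100, 300), c(0.5, 0.5))
  m <- convert_weighting(d, "mass")
  masses <- m$density * fibrilhydro:::node_weights(m$grid)
  expect_equal(unname(masses), c(0.25, 0.75), tolerance = 1e-12)
  expect_identical(m$weighting, "mass")
})

test_that("extinction and mass weighting are identical; round trips are exact", {
  d <- afm_mass_dist(seed = 5, n = 500)
  e <- convert_weighting(d, "extinction")
  expect_equal(e$density, d$density, tolerance = 1e-15)
  # mass -> number -> mass round trip
  back <- convert_weighting(convert_weighting(d, "number"), "mass")
  expect_equal(back$density, d$density, tolerance = 1e-12)
  expect_error(convert_weighting(d, "volume"), "unknown weighting")
})

test_that("every conversion and mapping conserves unit weight", {
  d <- afm_mass_dist(seed = 9, n = 800)
  expect_equal(trap_integral(d), 1, tolerance = 1e-9)
  expect_equal(trap_integral(convert_weighting(d, "number")), 1,
               tolerance = 1e-9)
  s <- length_dist_to_s_dist(d, 4.7)
  expect_equal(trap_integral(s), 1, tolerance = 1e-9)
  back <- s_dist_to_length_dist(s, 4.7)
  expect_equal(trap_integral(back), 1, tolerance = 1e-9)
})

test_that("a delta-like length maps to the forward-model s and back", {
  d <- weighted_distribution(c(499.99, 500, 500.01), c(0, 1, 0) + 1e-9)
  s <- length_dist_to_s_dist(d, 4.7)
  expect_equal(s$grid[which.max(s$density)],
               sedimentation_coefficient(500, 4.7), tolerance = 1e-6)
  back <- s_dist_to_length_dist(s, 4.7)
  expect_equal(back$grid[which.max(back$density)], 500, tolerance = 1e-6)
})

test_that("l <-> s round trip is the identity on the CDF", {
  d <- afm_mass_dist(seed = 11)
  s <- length_dist_to_s_dist(d, 4.7)
  back <- s_dist_to_length_dist(s, 4.7)
  expect_equal(back$grid, d$grid, tolerance = 1e-9)
  expect_lt(cdf_sup_distance(d, back), 1e-6)
})

test_that("quantiles are equivariant under the monotone l -> s mapping", {
  d <- afm_mass_dist(seed = 13, n = 1000)
  s <- length_dist_to_s_dist(d, 4.7)
  ql <- summary(d)
  qs <- summary(s)
  for (f in c("q10", "median", "q90")) {
    expect_equal(qs[[f]],
                 sedimentation_coefficient(ql[[f]], 4.7), tolerance = 5e-3)
  }
})

test_that("weighting conversion commutes with the l -> s mapping", {
  d <- afm_mass_dist(seed = 17, n = 600)
  a <- length_dist_to_s_dist(convert_weighting(d, "number"), 4.7)
  b <- convert_weighting(length_dist_to_s_dist(d, 4.7), "number",
                         height = 4.7)
  expect_equal(a$grid, b$grid, tolerance = 1e-9)
  expect_lt(max(abs(a$density - b$density) / max(a$density)), 1e-8)
})

test_that("s grid below the rod limit is excluded and reported", {
  s_min <- sedimentation_coefficient(4.7, 4.7)
  grid <- seq(s_min * 0.2, 40, length.out = 100)
  d <- weighted_distribution(grid, rep(1, 100), axis = "s",
                             weighting = "mass")
  expect_message(out <- s_dist_to_length_dist(d, 4.7), "excluded")
  expect_gt(out$metadata$excluded_weight, 0)
  expect_true(all(out$grid >= 4.7))
  low <- weighted_distribution(seq(s_min * 0.05, s_min * 0.5, length.out = 10),
                               rep(1, 10), axis = "s")
  expect_error(s_dist_to_length_dist(low, 4.7), "below the q = 1 limit")
})

test_that("summary: symmetric triangle, delta limit, and the AFM fixture mean", {
  g <- seq(0.01, 2, length.out = 201)
  tri <- weighted_distribution(g, pmax(1 - abs(g - 1), 0))
  s <- summary(tri)
  expect_equal(s$mode, 1, tolerance = 0.02)
  expect_equal(s$mean, 1, tolerance = 0.02)
  expect_equal((s$q90 - 1), (1 - s$q10), tolerance = 0.02)

  delta <- weighted_distribution(100, 1, normalize = FALSE)
  sd <- summary(delta)
  expect_true(all(c(sd$q10, sd$q50, sd$q90, sd$mode) == 100))

  # lognormal fixture on [80, 810] nm mimicking the reported sample:
  # mean fibril length within 2% of 395 nm
  d <- afm_mass_dist(seed = 42)
  expect_equal(summary(convert_weighting(d, "number"))$mean, 395,
               tolerance = 0.02)
})

test_that("AFM-like fixtures map to modal s in the experimentally seen range", {
  # fibril samples with mean lengths across 300-600 nm all give modal s
  # within the reported 25-42 S window at h = 4.7 nm, densified material
  for (mean_nm in c(300, 450, 600)) {
    x <- generate_afm_fixture(n = 1500, mean_nm = mean_nm,
                              bounds = c(60, 2.2 * mean_nm), seed = 3)
    d <- convert_weighting(
      suppressMessages(ingest_length_table(x$length_nm)), "mass")
    s <- length_dist_to_s_dist(d, 4.7)
    expect_gt(summary(s)$mode, 25 * 0.99)
    expect_lt(summary(s)$mode, 42 * 1.01)
  }
})

test_that("constructor rejects malformed distributions", {
  expect_error(weighted_distribution(c(2, 1), c(1, 1)), "strictly increasing")
  expect_error(weighted_distribution(c(1, 2), c(-1, 1)), "non-negative")
  expect_error(weighted_distribution(c(-1, 2), c(1, 1)), "positive")
  expect_error(weighted_distribution(c(1, 2), c(0, 0)), "zero total weight")
})
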