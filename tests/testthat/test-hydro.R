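# Cylinder hydrodynamics: frictional-ratio polynomial, equivalent sphere,
# forward and inverse sedimentation model.

test_that("frictional ratio polynomial matches its anchors", {
  # sphere limit: the constant term
  expect_identical(friction_ratio(1), 1.0304)
  # k = 1: term-by-term sum of the printed coefficients
  expect_equal(friction_ratio(exp(1)),
               1.0304 + 0.0193 + 0.06229 + 0.00476 + 0.00166 + 2.66e-6,
               tolerance = 1e-12)
  # a fibril-like aspect ratio, frozen from direct polynomial evaluation
  expect_equal(friction_ratio(106.383), 3.876939, tolerance = 1e-6)
})

test_that("frictional ratio rejects disks and non-finite input", {
  expect_error(friction_ratio(0.5), "q >= 1")
  expect_error(friction_ratio(NaN), "finite")
  expect_error(friction_ratio(Inf), "finite")
})

test_that("frictional ratio is non-decreasing for rods", {
  q <- 10^seq(0, 4, length.out = 200)
  expect_true(all(diff(friction_ratio(q)) >= 0))
})

test_that("equivalent-sphere diameter equals the equal-volume sphere", {
  # 500 x 4.7 nm: solve pi h^2 l / 4 = pi d^3 / 6 directly
  d_direct <- (6 / pi * pi / 4 * (4.7e-9)^2 * 500e-9)^(1 / 3)
  expect_equal(equivalent_sphere_diameter(500e-9, 4.7e-9), d_direct,
               tolerance = 1e-12)
  expect_equal(d_direct * 1e9, 25.49289, tolerance = 1e-6)
  # q = 1 closed form
  h <- 8e-9
  expect_equal(equivalent_sphere_diameter(h, h), (3 / 2)^(1 / 3) * h,
               tolerance = 1e-12)
  # scaling law: doubling l multiplies d_eq by 2^(1/3)
  expect_equal(equivalent_sphere_diameter(1000e-9, 4.7e-9) /
                 equivalent_sphere_diameter(500e-9, 4.7e-9),
               2^(1 / 3), tolerance = 1e-12)
})

test_that("forward model reproduces the step-by-step Stokes oracle", {
  # independent oracle: equivalent sphere + Hansen drag assembled by hand
  h <- 4.7e-9; l <- 500e-9
  deq <- (3 * h^2 * l / 2)^(1 / 3)
  ffo <- friction_ratio(l / h)
  s_oracle <- deq^2 * (1.02 * 1331.6 - 998.2) / (18 * 1.002e-3 * ffo)
  expect_equal(sedimentation_coefficient(500, 4.7), s_oracle / 1e-13,
               tolerance = 1e-12)
  expect_equal(sedimentation_coefficient(500, 4.7), 33.46185,
               tolerance = 1e-6)
  # unit switch
  expect_equal(sedimentation_coefficient(500, 4.7, unit = "s"), s_oracle,
               tolerance = 1e-12)
})

test_that("neutral buoyancy gives exactly zero with a warning", {
  mat <- fibril_material(base_density = 998.2, densification = 1)
  expect_warning(s <- sedimentation_coefficient(500, 4.7, mat), "neutral")
  expect_identical(s, 0)
})

test_that("s is linear in the density contrast", {
  solv <- solvent_conditions()
  m1 <- fibril_material(densification = 1)
  m2 <- fibril_material(densification = 1.02)
  s1 <- sedimentation_coefficient(500, 4.7, m1, solv)
  s2 <- sedimentation_coefficient(500, 4.7, m2, solv)
  expect_equal(s2 / s1,
               (1.02 * 1331.6 - 998.2) / (1331.6 - 998.2),
               tolerance = 1e-12)
  # doubling the contrast doubles s at fixed geometry
  solv_light <- solvent_conditions(density = 1331.6 - 2 * (1331.6 - 998.2))
  expect_equal(sedimentation_coefficient(500, 4.7, m1, solv_light),
               2 * s1, tolerance = 1e-12)
})

test_that("s increases strictly with length at fixed height", {
  for (h in c(2, 4.7, 6)) {
    l <- exp(seq(log(h), log(1000 * h), length.out = 120))
    s <- sedimentation_coefficient(l, h)
    expect_true(all(diff(s) > 0), info = sprintf("height %g nm", h))
  }
})

test_that("inverse model inverts the forward model to 1e-9 relative", {
  for (h in c(2, 4.7, 6)) {
    l <- seq(50, 2000, length.out = 25)
    l <- l[l >= h]
    s <- sedimentation_coefficient(l, h)
    l_back <- length_from_s(s, h)
    expect_lt(max(abs(l_back - l) / l), 1e-9)
  }
  # the worked inversion example
  expect_equal(length_from_s(33.46185, 4.7), 500, tolerance = 1e-5)
})

test_that("inverse model handles the q = 1 boundary and rejects below it", {
  h <- 4.7
  s_min <- sedimentation_coefficient(h, h)
  expect_equal(length_from_s(s_min, h), h, tolerance = 1e-9)
  expect_error(length_from_s(s_min * 0.5, h), "no rod solution")
  expect_error(length_from_s(-1, h), "s must be > 0")
})

test_that("cylinder molar mass matches direct volume x density", {
  # circular cross-section of radius 5 nm (diameter 10 nm), 500 nm long
  m <- 1331.6 * pi / 4 * (10e-9)^2 * 500e-9 * 6.02214076e26
  expect_equal(cylinder_molar_mass(500, 10), m, tolerance = 1e-12)
  expect_equal(cylinder_molar_mass(500, 10) / 1e6, 31.49, tolerance = 1e-3)
  # taking the printed 5 nm literally as the diameter: ~7.9 MDa
  expect_equal(cylinder_molar_mass(500, 5) / 1e6, 7.873, tolerance = 1e-3)
  expect_identical(cylinder_molar_mass(0, 10), 0)
})

test_that("geometry constructor enforces rod invariants", {
  expect_error(cylinder_geometry(-1e-9, 4.7e-9), "> 0")
  expect_error(cylinder_geometry(2e-9, 4.7e-9), "q = length/height")
  g <- cylinder_geometry(500e-9, 4.7e-9)
  expect_equal(g$aspect_ratio, 500 / 4.7, tolerance = 1e-12)
  expect_equal(g$k, log(500 / 4.7), tolerance = 1e-12)
})
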