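# Shape representation, kinematics and footprint geometry.

test_that("reference cell is the identity map with exact circular footprint", {
  p <- test_params(R0 = 20, RN = 6)
  ref <- make_reference_cell(p)
  expect_equal(ref$coefficients, rep(0, 20))

  mf <- evaluate_kinematics(ref, p)
  expect_true(all(abs(mf$points$J - 1) < 1e-12))
  expect_true(all(abs(mf$points$lambda_I - 1) < 1e-12))
  expect_true(all(abs(mf$eps) < 1e-12))

  # quadrature area exact to 1e-10 relative
  expect_equal(footprint_area(ref, p, method = "quadrature"), pi * 400,
               tolerance = 1e-10)
  expect_equal(footprint_area(ref, p, method = "boundary"), pi * 400,
               tolerance = 1e-8)
  # nucleus footprint
  expect_equal(footprint_area(ref, p, method = "boundary", radius = 6),
               pi * 36, tolerance = 1e-8)
  expect_equal(footprint_moments(ref, p)$aspect_ratio, 1, tolerance = 1e-8)
})

test_that("affine maps give the expected stretches and fibre strains", {
  p <- test_params()
  # uniform 1.2x dilation
  dil <- shape_state(c(0.2, 0, 0, 0.2, rep(0, 16)))
  mf <- evaluate_kinematics(dil, p)
  expect_true(all(abs(mf$points$lambda_I - 1.2) < 1e-12))
  expect_true(all(abs(mf$points$lambda_II - 1.2) < 1e-12))
  expect_true(all(abs(mf$eps - 0.2) < 1e-12))

  # simple shear F = [[1, 0.3], [0, 1]]: principal stretches are the
  # singular values (independent SVD oracle)
  sh <- shape_state(c(0, 0.3, 0, 0, rep(0, 16)))
  mf <- evaluate_kinematics(sh, p)
  sv <- svd(matrix(c(1, 0, 0.3, 1), 2, 2))$d
  expect_true(all(abs(mf$points$lambda_I - sv[1]) < 1e-12))
  expect_true(all(abs(mf$points$lambda_II - sv[2]) < 1e-12))
})

test_that("boundary-integral area matches quadrature of J for smooth maps", {
  p <- test_params()
  for (seed in 1:5) {
    sh <- test_shape(amplitude = 0.12, seed = seed)
    a1 <- footprint_area(sh, p, method = "boundary")
    a2 <- footprint_area(sh, p, method = "quadrature")
    expect_lt(abs(a1 - a2) / a2, 1e-6)
  }
})

test_that("degenerate maps are rejected as invalid microstates", {
  p <- test_params()
  flat <- shape_state(c(-1.5, 0, 0, 0, rep(0, 16)))  # det F < 0 region
  expect_error(evaluate_kinematics(flat, p), "orientation-preserving")
  expect_error(gibbs(flat, env_elastic(30), p), "invalid microstate")
})

test_that("island confinement check follows the geometry", {
  p <- test_params(R0 = 20)
  island <- env_island(2025)  # side 45 um
  ref <- make_reference_cell(p)
  expect_true(footprint_inside_island(ref, island, p))    # diameter 40 < 45

  big <- shape_state(c(0.25, 0, 0, 0.25, rep(0, 16)))     # radius 25
  expect_false(footprint_inside_island(big, island, p))   # diameter 50 > 45

  # axis-aligned ellipse with semi-axes (30, 10): major axis 60 > 45
  ell <- shape_state(c(0.5, 0, 0, -0.5, rep(0, 16)))
  expect_false(footprint_inside_island(ell, island, p))
  b <- footprint_boundary(ell, p)
  expect_equal(max(b$x1), 30, tolerance = 1e-10)
  expect_equal(max(b$x2), 10, tolerance = 1e-10)
})

test_that("confinement is monotone in island area", {
  p <- test_params()
  areas <- c(1600, 2025, 2725, 4900)
  for (seed in 1:6) {
    sh <- test_shape(amplitude = 0.25, seed = seed)
    ok <- vapply(areas, function(a)
      footprint_inside_island(sh, env_island(a), p), TRUE)
    # once inside, stays inside for all larger areas
    expect_true(all(diff(as.integer(ok)) >= 0))
  }
})

test_that("footprint moments recover exact ellipse aspect ratios", {
  p <- test_params()
  ell <- shape_state(c(0.5, 0, 0, -0.5, rep(0, 16)))  # semi-axes 30, 10
  m <- footprint_moments(ell, p)
  expect_equal(m$aspect_ratio, 3, tolerance = 1e-6)
  expect_equal(m$area, pi * 30 * 10, tolerance = 1e-6)
})
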