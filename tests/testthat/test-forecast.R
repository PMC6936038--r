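# CLT band classifier: density, band probabilities, normalization,
# forecasting and band calibration.

test_that("fbar_density is the CLT Gaussian with variance sigma^2/Nc", {
  f1 <- fbar_density(2, 0.6, 1)
  expect_equal(f1(2.3), dnorm(2.3, 2, 0.6), tolerance = 1e-12)
  f15 <- fbar_density(2, 0.6, 15)
  expect_equal(f15(2.1), dnorm(2.1, 2, 0.6 / sqrt(15)), tolerance = 1e-12)
  expect_equal(integrate(f15, -Inf, Inf)$value, 1, tolerance = 1e-10)
  expect_error(fbar_density(2, 0, 15), "sigma")
})

test_that("lineage probability equals quadrature of the CLT density over the band", {
  # the worked case: mu = 2.0, sigma = 0.6, Nc = 15, band 1.87 +/- 0.05
  band <- lineage_band("myoblast", 1.87, 0.05)
  px <- lineage_probability(2.0, 0.6, 15, band)
  f <- fbar_density(2.0, 0.6, 15)
  xs <- seq(1.82, 1.92, length.out = 20001)
  quad <- sum(diff(xs) * (f(head(xs, -1)) + f(tail(xs, -1))) / 2)
  expect_equal(px, quad, tolerance = 1e-9)
  expect_equal(px, 0.180, tolerance = 1e-3)

  # randomized closed-form vs quadrature equivalence
  set.seed(1)
  for (i in 1:50) {
    mu <- runif(1, -3, 3); sg <- runif(1, 0.1, 2)
    Nc <- sample(1:40, 1)
    ctr <- runif(1, -3, 3); hw <- runif(1, 0, 1.5)
    b <- list(centre = ctr, half_width = hw)
    p1 <- lineage_probability(mu, sg, Nc, b)
    p2 <- integrate(fbar_density(mu, sg, Nc), ctr - hw, ctr + hw,
                    rel.tol = 1e-12, abs.tol = 1e-14)$value
    expect_equal(p1, p2, tolerance = 1e-10)
  }
})

test_that("band probability limits and monotonicity hold", {
  expect_identical(lineage_probability(2, 0.5, 15,
                                       list(centre = 1.9, half_width = 0)), 0)
  expect_equal(lineage_probability(2, 0.5, 15,
                                   list(centre = 2, half_width = 1e6)), 1)
  # non-decreasing in half-width
  hws <- seq(0, 2, by = 0.05)
  ps <- vapply(hws, function(h)
    lineage_probability(1.5, 0.4, 10, list(centre = 2, half_width = h)), 0)
  expect_true(all(diff(ps) >= -1e-14))
  # unimodal in mu with maximum at mu = centre
  mus <- seq(0, 4, by = 0.05)
  pm <- vapply(mus, function(m)
    lineage_probability(m, 0.4, 10, list(centre = 2, half_width = 0.3)), 0)
  expect_equal(mus[which.max(pm)], 2)
  expect_true(all(diff(pm[mus <= 2]) >= -1e-14))
  expect_true(all(diff(pm[mus >= 2]) <= 1e-14))
  expect_error(lineage_probability(2, 0.5, 15,
                                   list(centre = 2, half_width = -1)),
               "invalid band")
})

test_that("Z_L normalization covers both branches and errors on bad input", {
  a <- normalize_lineages(c(osteoblast = 0.5, myoblast = 0.3))
  expect_identical(a$Z_L, 1)
  expect_equal(unname(a$p), c(0.5, 0.3))
  expect_equal(a$undifferentiated, 0.2)

  b <- normalize_lineages(c(0.9, 0.6))
  expect_equal(b$Z_L, 1.5)
  expect_equal(unname(b$p), c(0.6, 0.4))
  expect_equal(b$undifferentiated, 0)

  c0 <- normalize_lineages(c(0, 0))
  expect_equal(c0$undifferentiated, 1)
  expect_error(normalize_lineages(c(1.2, 0.1)), "\\[0, 1\\]")

  # probabilities plus undifferentiated always sum to one
  set.seed(2)
  for (i in 1:100) {
    raw <- runif(sample(1:4, 1))
    nz <- normalize_lineages(raw)
    expect_equal(sum(nz$p) + nz$undifferentiated, 1, tolerance = 1e-12)
    expect_gte(nz$undifferentiated, 0)
  }
})

test_that("forecast() combines ensemble statistics and bands coherently", {
  toy <- toy_ensemble_spec(G = seq(0, 2, length.out = 21),
                           F_cyto = seq(1.4, 2.6, length.out = 21))
  ens <- make_toy_ensemble(toy, zeta = 0.4, n = 5000, seed = 11)
  mm <- media_model(dplyr::bind_rows(
    lineage_band("osteoblast", 2.0, 0.2),
    lineage_band("myoblast", 1.6, 0.1)), Nc = 15, media = "toy")
  fc <- forecast(ens, mm)
  expect_setequal(fc$lineage, c("osteoblast", "myoblast", "undifferentiated"))
  expect_equal(sum(fc$p), 1, tolerance = 1e-12)
  st <- ensemble_statistics(ens, "F_cyto")
  expect_equal(unname(fc$p_raw[fc$lineage == "osteoblast"]),
               lineage_probability(st$mean, st$sd, 15, mm[1, ]),
               tolerance = 1e-12)
  expect_true(all(fc$se[!is.na(fc$se)] >= 0))
  expect_error(forecast(tibble::tibble(x = 1:5), mm), "F_cyto")
})

test_that("calibrate_bands recovers generating bands from noiseless fractions", {
  set.seed(5)
  stats_df <- tibble::tibble(condition = 1:6,
                             mu = c(1.2, 1.6, 2.0, 2.4, 2.8, 3.2),
                             sigma = rep(0.5, 6))
  truth <- list(osteoblast = c(2.59, 0.14), myoblast = c(1.87, 0.05))
  observed <- dplyr::bind_rows(lapply(names(truth), function(lg) {
    tibble::tibble(
      condition = stats_df$condition, lineage = lg,
      fraction = lineage_probability(stats_df$mu, stats_df$sigma, 15,
                                     list(centre = truth[[lg]][1],
                                          half_width = truth[[lg]][2])))
  }))
  mm <- calibrate_bands(stats_df, observed, Nc = 15)
  fit <- attr(mm, "fit")
  for (lg in names(truth)) {
    expect_equal(mm$centre[mm$lineage == lg], truth[[lg]][1],
                 tolerance = 1e-3)
    expect_equal(mm$half_width[mm$lineage == lg], truth[[lg]][2],
                 tolerance = 1e-3)
  }
  expect_lt(max(fit$sse), 1e-6)
})

test_that("calibrate_bands limiting geometry and error cases", {
  # single lineage, two conditions with fractions {1 - eps, eps}:
  # the fitted band brackets the first condition's mu
  stats_df <- tibble::tibble(condition = 1:2, mu = c(1.0, 2.0),
                             sigma = c(0.3, 0.3))
  observed <- tibble::tibble(condition = 1:2, lineage = "osteoblast",
                             fraction = c(0.98, 0.02))
  mm <- calibrate_bands(stats_df, observed, Nc = 15)
  expect_lt(mm$centre - mm$half_width, 1.0)
  expect_gt(mm$centre + mm$half_width, 1.0)

  expect_error(
    calibrate_bands(stats_df[1, ], observed[1, ], Nc = 15),
    ">= 2 conditions")
})

test_that("reference media models carry the published band values", {
  gm <- growth_media()
  expect_equal(gm$centre[gm$lineage == "osteoblast"], 2.59)
  expect_equal(gm$half_width[gm$lineage == "osteoblast"], 0.14)
  expect_equal(gm$centre[gm$lineage == "myoblast"], 1.87)
  expect_equal(gm$half_width[gm$lineage == "myoblast"], 0.05)
  expect_identical(attr(gm, "Nc"), 15L)
  mx <- mixed_media()
  expect_equal(mx$centre[mx$lineage == "adipocyte"], 1.61)
  expect_equal(mx$half_width[mx$lineage == "adipocyte"], 0.44)
  expect_equal(mx$half_width[mx$lineage == "osteoblast"], 0.37)
})
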