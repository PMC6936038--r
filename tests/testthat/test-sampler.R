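# Metropolis machinery and the homeostatic zeta solve, validated against
# exact enumeration oracles on toy state spaces.

tv_distance <- function(emp, exact) sum(abs(emp - exact)) / 2

test_that("toy Metropolis chain reproduces the exact Boltzmann distribution", {
  toy <- toy_ensemble_spec(c(0, 1, 2))
  zeta <- 0.31
  idx <- toy_metropolis(toy, zeta, n_steps = 1e5, seed = 4)
  emp <- tabulate(idx, 3) / length(idx)
  expect_lt(tv_distance(emp, toy_peq(toy, zeta)), 0.02)

  # zero-coupling limit: uniform
  idx0 <- toy_metropolis(toy, 0, n_steps = 1e5, seed = 5)
  expect_lt(tv_distance(tabulate(idx0, 3) / length(idx0), rep(1 / 3, 3)),
            0.02)

  # single-state space: chain is constant
  one <- toy_ensemble_spec(3.7)
  expect_true(all(toy_metropolis(one, 1, 1000, seed = 1) == 1L))
})

test_that("solve_zeta on enumerable spaces matches the scalar bisection oracle", {
  toy <- toy_ensemble_spec(c(0, 1, 2), G_S = 0.8)
  z <- solve_zeta(toy)
  # independent oracle: bisect (e^-z + 2 e^-2z)/(1 + e^-z + e^-2z) = 0.8
  oracle <- uniroot(function(z) {
    w <- exp(-z * c(0, 1, 2))
    sum(w * c(0, 1, 2)) / sum(w) - 0.8
  }, c(-5, 5), tol = 1e-12)$root
  expect_equal(z, oracle, tolerance = 1e-6)
  expect_equal(toy_mean_G(toy, z), 0.8, tolerance = 1e-8)

  # degenerate space: constraint holds for every zeta; documented tie-break
  expect_identical(solve_zeta(toy_ensemble_spec(c(1.5, 1.5), G_S = 1.5)), 1)

  # unreachable target mean
  expect_error(solve_zeta(toy_ensemble_spec(c(0, 1, 2), G_S = -0.1)),
               "reachable")
})

test_that("ensemble_statistics summarizes toy chains consistently with enumeration", {
  toy <- toy_ensemble_spec(c(0, 0.7, 1.1, 2.3), G_S = 1)
  zeta <- solve_zeta(toy)
  ens <- make_toy_ensemble(toy, zeta = zeta, n = 20000, seed = 9)
  st <- ensemble_statistics(ens, "G")
  exact_mean <- toy_mean_G(toy, zeta)
  expect_lt(abs(st$mean - exact_mean), 3 * st$se_mean + 1e-12)
  expect_equal(exact_mean, 1, tolerance = 1e-8)  # by construction of zeta

  # constant observable: zero variance, density concentrated at the value
  cens <- tibble::tibble(F_cyto = rep(2.5, 100))
  stc <- ensemble_statistics(cens, "F_cyto")
  expect_identical(stc$var, 0)
  expect_lt(max(abs(stc$density$x - 2.5)), 1e-3)

  expect_error(ensemble_statistics(ens, "no_such_column"), "not found")
})

test_that("Monte-Carlo standard errors shrink like 1/sqrt(n)", {
  toy <- toy_ensemble_spec(c(0, 1, 2, 3))
  e1 <- make_toy_ensemble(toy, zeta = 0.5, n = 4000, seed = 2)
  e2 <- make_toy_ensemble(toy, zeta = 0.5, n = 16000, seed = 3)
  r <- ensemble_statistics(e1, "G")$se_mean /
    ensemble_statistics(e2, "G")$se_mean
  expect_gt(r, 1.5); expect_lt(r, 2.7)   # ~2 with stochastic tolerance
})

test_that("cell-model chains are reproducible bitwise from the seed", {
  p <- test_params_gs()
  env <- env_elastic(30)
  e1 <- metropolis_chain(env, p, zeta = 1, n_steps = 1200, seed = 33)
  e2 <- metropolis_chain(env, p, zeta = 1, n_steps = 1200, seed = 33)
  expect_identical(attr(e1, "coefficients"), attr(e2, "coefficients"))
  expect_identical(e1$G, e2$G)
  e3 <- metropolis_chain(env, p, zeta = 1, n_steps = 1200, seed = 34)
  expect_false(identical(e1$G, e3$G))
})

test_that("island chains never leave the island and respect energies", {
  p <- test_params_gs()
  env <- env_island(2025)
  e <- cached("chain_island_2025",
              metropolis_chain(env, p, zeta = 1, n_steps = 3000, seed = 8))
  expect_true(all(e$A_hat * pi * p$R0^2 <= 2025 + 1e-9))
  co <- attr(e, "coefficients")
  for (i in c(1, nrow(co))) {
    expect_true(footprint_inside_island(shape_state(co[i, ]), env, p,
                                        n = 72L))
  }
  # stored energies are recomputable from the stored shapes
  b <- gibbs(ensemble_shape(e, nrow(e)), env, p)
  expect_equal(b$G, e$G[nrow(e)], tolerance = 1e-12)
})

test_that("solve_zeta on the cell model satisfies the homeostatic constraint", {
  p <- test_params_gs()
  e <- cached("ens_30_quick",
              suppressWarnings(solve_zeta(env_elastic(30), p, seed = 21,
                                          n_steps = 8000,
                                          pilot_steps = 2500)))
  gap <- abs(mean(e$G) - p$G_S)
  st <- ensemble_statistics(e, "G")
  expect_lt(gap, max(0.01 * abs(p$G_S), 4 * st$se_mean))
  expect_gt(attr(e, "zeta"), 0)
  # monotonicity of the solve path: var(G) >= 0 implies mean decreases in zeta
  path <- attr(e, "diagnostics")$solve_path
  expect_true(all(path[, "var_G"] >= 0))
})
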