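# Energy model: passive elasticity, cytoskeletal equilibrium, substrate
# tractions, composition, and the suspension reference state.

test_that("passive energy matches the closed-form Ogden density for uniform dilation", {
  # single-region disc (nucleus modulus set equal to cytoplasm)
  p <- test_params(mu_n = 1, mu_c = 1, kappa = 1)
  lam <- 1.2
  sh <- shape_state(c(lam - 1, 0, 0, lam - 1, rep(0, 16)))
  mf <- evaluate_kinematics(sh, p)
  Phi <- (2 * p$mu_c / p$m^2) * (2 * lam^p$m - 2 - p$m * log(lam^2)) +
    p$kappa / 2 * (lam^2 - 1)^2
  expected <- p$t0 * Phi * pi * p$R0^2 / p$E_norm
  expect_equal(passive_energy(mf, p), expected, tolerance = 1e-10)
  expect_gt(expected, 0)
})

test_that("passive energy is zero at identity, positive and linear in mu elsewhere", {
  p1 <- test_params(mu_n = 2, mu_c = 2, kappa = 1e-12)
  p2 <- test_params(mu_n = 4, mu_c = 4, kappa = 1e-12)
  ref <- make_reference_cell(p1)
  expect_equal(passive_energy(evaluate_kinematics(ref, p1), p1), 0)
  sh <- test_shape(0.2, seed = 3)
  e1 <- passive_energy(evaluate_kinematics(sh, p1), p1)
  e2 <- passive_energy(evaluate_kinematics(sh, p2), p2)
  expect_gt(e1, 0)
  expect_equal(e2 / e1, 2, tolerance = 1e-9)
})

test_that("passive energy is non-negative under compression as well", {
  p <- test_params()
  for (lam in c(0.6, 0.85, 1.0, 1.3)) {
    sh <- shape_state(c(lam - 1, 0, 0, lam - 1, rep(0, 16)))
    expect_gte(passive_energy(evaluate_kinematics(sh, p), p), 0)
  }
})

test_that("cytoskeletal equilibrium conserves protein and is isotropic under symmetric inputs", {
  p <- test_params()
  mf <- evaluate_kinematics(make_reference_cell(p), p)
  cy <- cytoskeleton_equilibrium(mf, p)
  expect_lt(cy$conservation_residual, 1e-8)
  expect_true(cy$N_u > 0 && cy$N_u < 1)
  # equibiaxial (here zero) strain: eta independent of phi at every point
  expect_lt(max(apply(cy$eta, 1, function(r) diff(range(r)))), 1e-12)

  # sigma_max = 0: binding advantage uniform and negative, eta isotropic
  cy0 <- cytoskeleton_equilibrium(mf, p, sigma_max = 0)
  expect_true(all(cy0$Psi < 0))
  expect_lt(max(apply(cy0$eta, 1, function(r) diff(range(r)))), 1e-12)

  # dilated state stays conservative
  cy2 <- cytoskeleton_equilibrium(
    evaluate_kinematics(shape_state(c(0.3, 0, 0, 0.3, rep(0, 16))), p), p)
  expect_lt(cy2$conservation_residual, 1e-8)
})

test_that("N_u solves the scalar conservation equation (bisection oracle)", {
  p <- test_params()
  lam <- 1.25
  sc <- 0.8
  mf <- evaluate_kinematics(shape_state(c(lam - 1, 0, 0, lam - 1,
                                          rep(0, 16))), p)
  cy <- cytoskeleton_equilibrium(mf, p, sig_scale = sc)
  # uniform state: conservation reduces to one scalar equation
  eps <- lam - 1
  sig <- p$sigma_max * sc * min(1, max(0, 1 + p$beta * eps))
  Psi <- (sig * p$Omega - p$mu_b0) / p$kT_hat
  W <- exp(Psi)
  nf <- max(1 + eps, p$n_min)
  g <- function(Nu) Nu + (Nu * W / (1 + Nu * W)) * p$eta_max * nf - 1
  Nu_oracle <- uniroot(g, c(1e-12, 1), tol = 1e-14)$root
  expect_equal(cy$N_u, Nu_oracle, tolerance = 1e-8)
})

test_that("cytoskeletal energy matches the arithmetic oracle for a uniform state", {
  p <- test_params()
  lam <- 1.15
  mf <- evaluate_kinematics(shape_state(c(lam - 1, 0, 0, lam - 1,
                                          rep(0, 16))), p)
  cy <- cytoskeleton_equilibrium(mf, p)
  val <- cytoskeleton_energy(cy, mf, p)
  eps <- lam - 1
  sig <- p$sigma_max * min(1, max(0, 1 + p$beta * eps))
  Psi <- (sig * p$Omega - p$mu_b0) / p$kT_hat
  frac <- cy$N_u * exp(Psi) / (1 + cy$N_u * exp(Psi))
  nf <- max(1 + eps, p$n_min)
  en <- p$eta_max * frac * nf
  expected <- p$C_cyto *
    (cy$N_u * (log(cy$N_u) - 1) + en * (log(frac * nf) - 1 - Psi)) /
    p$E_norm
  expect_equal(val, expected, tolerance = 1e-8)
})

test_that("cytoskeleton_energy refuses a non-equilibrium state", {
  p <- test_params()
  mf <- evaluate_kinematics(make_reference_cell(p), p)
  cy <- cytoskeleton_equilibrium(mf, p)
  cy$conservation_residual <- 1  # simulate a broken input
  expect_error(cytoskeleton_energy(cy, mf, p), "conservation")
})

test_that("raising polymerization lowers the cytoskeletal free energy", {
  p <- test_params_gs()
  env <- env_island(4900)
  ctx <- model_context(p, env)
  for (seed in 1:4) {
    sh <- test_shape(0.12, seed = seed)
    lo <- gibbs(sh, env, p, ctx = ctx, sigma_max = 231)
    mid <- gibbs(sh, env, p, ctx = ctx, sigma_max = 240)
    hi <- gibbs(sh, env, p, ctx = ctx, sigma_max = 260)
    # more contractile -> more bound -> lower F_cyto (same shape)
    expect_gt(mid$N_b, lo$N_b)
    expect_gt(hi$N_b, mid$N_b)
    expect_lt(mid$F_cyto, lo$F_cyto)
    expect_lt(hi$F_cyto, mid$F_cyto)
  }
})

test_that("compiled kernel and plain-R energy paths agree", {
  p <- test_params_gs()
  for (E in c(3, 30)) {
    env <- env_elastic(E)
    ctx <- model_context(p, env)
    sc <- E / (E + p$E_half)
    for (seed in 1:3) {
      sh <- test_shape(0.15, seed = seed)
      b <- gibbs(sh, env, p, ctx = ctx)
      mf <- evaluate_kinematics(sh, p)
      expect_equal(b$F_passive, passive_energy(mf, p), tolerance = 1e-9)
      cy <- cytoskeleton_equilibrium(mf, p, sig_scale = sc)
      expect_equal(b$N_u, cy$N_u, tolerance = 1e-7)
      expect_equal(b$F_cyto, cytoskeleton_energy(cy, mf, p),
                   tolerance = 1e-6)
    }
  }
})

test_that("substrate energy and tractions behave per the compliance model", {
  p <- test_params_gs()
  # rigid island: no stored substrate energy, ever
  isl <- env_island(4900)
  b <- gibbs(test_shape(0.1, seed = 2), isl, p)
  expect_identical(b$F_sub, 0)

  # zero-stress state: identity shape with sigma_max = 0
  p0 <- test_params(sigma_max = 0)
  s0 <- substrate_energy_and_tractions(make_reference_cell(p0),
                                       env_elastic(30), p0)
  expect_lt(max(s0$tractions$T_mag), 1e-10)
  expect_equal(s0$F_sub, 0, tolerance = 1e-12)

  # F_sub equals the Winkler quadrature of the returned traction field
  env <- env_elastic(10)
  st <- substrate_energy_and_tractions(test_shape(0.15, seed = 5), env, p)
  k <- p$winkler_c * env$E_sub / p$R0
  fsub_from_T <- with(st$tractions, sum(w * J * T_mag^2)) / (2 * k * p$E_norm)
  expect_equal(st$F_sub, fsub_from_T, tolerance = 1e-10)
  # and the single-patch closed form is its building block
  expect_equal(winkler_energy(2, 100, 4, 1000), 2^2 * 100 / (2 * 4 * 1000))

  # net force and torque vanish
  expect_lt(st$force_residual, 1e-6)
  expect_lt(st$torque_residual, 1e-6)
})

test_that("Gibbs energy is an exact sum of its parts and favours stiffer substrates", {
  p <- test_params_gs()
  ctx3 <- model_context(p, env_elastic(3))
  ctx70 <- model_context(p, env_elastic(70))
  for (seed in 1:10) {
    sh <- test_shape(0.15, seed = seed)
    b <- gibbs(sh, env_elastic(3), p, ctx = ctx3)
    expect_identical(b$G - (b$F_passive + b$F_cyto + b$F_sub), 0)
    b70 <- gibbs(sh, env_elastic(70), p, ctx = ctx70)
    if (b$T_total > 1e-6) expect_lt(b70$G, b$G)
    expect_lt(b70$F_sub, b$F_sub)
  }
})

test_that("suspension state balances fibre tension against passive compression", {
  p <- test_params()
  s <- suspension_energy(p)
  expect_lt(s$lambda_s, 1)        # contracted by fibre tension
  expect_gt(s$lambda_s, 0.5)
  expect_equal(s$params$G_S, s$G_S)

  # no contractility: suspended state is the undeformed circle and
  # G_S is the cytoskeletal energy of that state
  p0 <- test_params(sigma_max = 0)
  s0 <- suspension_energy(p0)
  expect_identical(s0$lambda_s, 1)
  mf <- evaluate_kinematics(make_reference_cell(p0), p0)
  cy <- cytoskeleton_equilibrium(mf, p0)
  expect_equal(s0$G_S, cytoskeleton_energy(cy, mf, p0), tolerance = 1e-8)

  # normalization linearity: doubling E_norm halves G_S
  p2 <- test_params(E_norm = 2 * p$E_norm)
  expect_equal(suspension_energy(p2)$G_S, s$G_S / 2, tolerance = 1e-10)
})
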