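#' Normalized Gibbs free energy of a morphological microstate
#'
#' Composes the passive Ogden elastic energy, the cytoskeletal free
#' energy at stress-fibre chemical equilibrium, and the substrate
#' Helmholtz energy of the Winkler foundation into the total normalized
#' Gibbs energy `G = F_passive + F_cyto + F_sub` of the cell-substrate
#' system. For rigid adhesive islands the confinement constraint is
#' enforced and the substrate stores no energy.
#'
#' @param shape A [shape_state()].
#' @param env A [env_elastic()] or [env_island()] environment.
#' @param params A [cell_parameters()] object.
#' @param ctx Optional precomputed [model_context()] (built on demand).
#' @param sigma_max Optional override of the fibre tension ceiling, kPa
#'   (used for ROCK-inhibition runs).
#' @return An `energy_breakdown` list: `G`, `F_passive`, `F_cyto`,
#'   `F_sub` (all dimensionless), total normalized traction `T_total`,
#'   unbound fraction `N_u`, polymerization level `N_b = 1 - N_u`,
#'   deformed `area` (um^2), `aspect_ratio`, `min_J`, and force/torque
#'   residual diagnostics.
#' @examples
#' p <- cell_parameters()
#' b <- gibbs(make_reference_cell(p), env_elastic(30), p)
#' b$G - (b$F_passive + b$F_cyto + b$F_sub)  # 0 by construction
#' @export
gibbs <- function(shape, env, params, ctx = NULL, sigma_max = NULL) {
  stopifnot(inherits(shape, "shape_state"))
  if (is.null(ctx)) ctx <- model_context(params, env)
  v <- .energy_eval_cpp(shape$coefficients, unclass(ctx),
                        params_vector(params, sigma_max))
  if (v[["valid"]] != 1) {
    stop("invalid microstate: degenerate map or island confinement violated",
         call. = FALSE)
  }
  ev <- eigen(matrix(c(v[["Ixx"]], v[["Ixy"]], v[["Ixy"]], v[["Iyy"]]), 2, 2),
              symmetric = TRUE)$values
  structure(list(
    G = v[["G"]], F_passive = v[["F_passive"]], F_cyto = v[["F_cyto"]],
    F_sub = v[["F_sub"]], T_total = v[["T_total"]], N_u = v[["N_u"]],
    N_b = 1 - v[["N_u"]], area = v[["area"]],
    aspect_ratio = sqrt(ev[1] / max(ev[2], 1e-300)),
    min_J = v[["min_J"]], force_residual = v[["force_residual"]],
    torque_residual = v[["torque_residual"]]),
    class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown>\n")
  cat(sprintf("  G = %.4f  (F_passive = %.4f, F_cyto = %.4f, F_sub = %.4f)\n",
              x$G, x$F_passive, x$F_cyto, x$F_sub))
  cat(sprintf("  N_b = %.3f, T_total = %.4f, area = %.1f um^2, A_s = %.3f\n",
              x$N_b, x$T_total, x$area, x$aspect_ratio))
  invisible(x)
}

#' Passive elastic energy (compressible 2D Ogden)
#'
#' The passive contribution of cytoplasm, nucleus and lumped membrane
#' elasticity, from the energy density
#' `Phi = (2 mu / m^2)(lambda_I^m + lambda_II^m - 2 - m log J) +
#' (kappa/2)(J - 1)^2`, which is non-negative and vanishes only at the
#' identity. `mu` transitions smoothly from `mu_n` inside the nucleus to
#' `mu_c` in the cytoplasm over `interface_w`.
#'
#' This is a plain-R evaluation on the [evaluate_kinematics()] grid and
#' is deliberately independent of the compiled kernel (the test-suite
#' cross-checks the two).
#'
#' @param fields A `mechanical_fields` object from [evaluate_kinematics()].
#' @param params A [cell_parameters()] object.
#' @return Dimensionless energy (normalized by `E_norm`).
#' @export
passive_energy <- function(fields, params) {
  stopifnot(inherits(fields, "mechanical_fields"))
  p <- fields$points
  if (min(p$lambda_II) <= 0) stop("invalid state: non-positive stretch",
                                  call. = FALSE)
  s <- smoothstep((p$r - params$RN) / max(params$interface_w, 1e-12))
  mu <- params$mu_n + (params$mu_c - params$mu_n) * s
  m <- params$m
  Phi <- (2 * mu / m^2) * (p$lambda_I^m + p$lambda_II^m - 2 - m * log(p$J)) +
    params$kappa / 2 * (p$J - 1)^2
  params$t0 * sum(p$w * Phi) / params$E_norm
}

#' Stress-fibre chemical equilibrium
#'
#' Solves the coupled closure for the cytoskeleton state of a microstate:
#' (i) the Langmuir-type binding isotherm
#' `eta(x, phi) = eta_max N_u exp(Psi) / (1 + N_u exp(Psi))` with binding
#' advantage `Psi = (sigma Omega - mu_b0)/kT` and fibre tension
#' `sigma = sigma_max clamp(1 + beta eps, 0, 1)` (isometric tension ceiling
#' for stretched fibres, linear drop under shortening); (ii) the affine
#' functional-unit rule `n = max(1 + eps, n_min)`; and (iii) global
#' conservation of stress-fibre proteins,
#' `N_u + (1/A_ref) ∫∫ eta n dphi dA = 1`, solved for the single scalar
#' unknown `N_u` by bisection (the left side is strictly increasing in
#' `N_u`, so the root in (0, 1] is unique).
#'
#' @param fields A `mechanical_fields` object from [evaluate_kinematics()].
#' @param params A [cell_parameters()] object.
#' @param sigma_max Optional override of the fibre tension ceiling, kPa.
#' @param sig_scale Stall-tension ceiling factor of the environment
#'   (`E_sub/(E_sub + E_half)` on an elastic substrate, 1 on a rigid
#'   island; see [cell_parameters()]).
#' @return A list of class `cytoskeleton_state`: `eta` and `n_fib`
#'   (point x orientation matrices), `N_u`, `N_b = 1 - N_u`, `Psi`,
#'   and the conservation residual.
#' @export
cytoskeleton_equilibrium <- function(fields, params, sigma_max = NULL,
                                     sig_scale = 1) {
  stopifnot(inherits(fields, "mechanical_fields"))
  p <- fields$points
  smax <- if (is.null(sigma_max)) params$sigma_max else sigma_max
  s <- smoothstep((p$r - params$RN) / max(params$interface_w, 1e-12))
  etamax_q <- params$eta_max * s
  A_ref <- sum(p$w * s)
  sig <- smax * sig_scale * pmin(1, pmax(0, 1 + params$beta * fields$eps))
  dim(sig) <- dim(fields$eps)   # pmin/pmax drop the matrix shape
  Psi <- (sig * params$Omega - params$mu_b0) / params$kT_hat
  W <- exp(Psi)
  n_fib <- pmax(1 + fields$eps, params$n_min)
  dim(n_fib) <- dim(fields$eps)
  nphi <- length(fields$phi)
  bound_mean <- function(Nu) {
    fr <- Nu * W / (1 + Nu * W)
    sum(p$w * etamax_q * rowMeans(fr * n_fib)) / A_ref
  }
  g <- function(Nu) Nu + bound_mean(Nu) - 1
  if (g(1) < 0) stop("conservation equation has no root in (0, 1]",
                     call. = FALSE)
  Nu <- stats::uniroot(g, c(1e-12, 1), tol = 1e-14)$root
  eta <- etamax_q * (Nu * W / (1 + Nu * W))
  structure(list(eta = eta, n_fib = n_fib, N_u = Nu, N_b = 1 - Nu,
                 Psi = Psi, etamax_q = etamax_q, A_ref = A_ref,
                 conservation_residual = abs(g(Nu))),
            class = "cytoskeleton_state")
}

#' Cytoskeletal free energy
#'
#' The normalized free energy of the stress-fibre cytoskeleton at
#' chemical equilibrium: mixing entropy of the unbound pool plus the
#' standard free energy of the bound fibres minus the mechanical work of
#' fibre tension,
#' `F_cyto = (C_cyto / E_norm) [ N_u (ln N_u - 1) +
#' (1/A_ref) ∫∫ eta n (ln(eta n / eta_max) - 1 - Psi) dphi dA ]`.
#' Raising the polymerization level `N_b` at fixed strain (for example by
#' raising `sigma_max`) strictly lowers this energy; that property is
#' verified by the test-suite rather than assumed.
#'
#' @param cyto A `cytoskeleton_state` from [cytoskeleton_equilibrium()].
#' @param fields The matching `mechanical_fields`.
#' @param params A [cell_parameters()] object.
#' @return Dimensionless energy (normalized by `E_norm`).
#' @export
cytoskeleton_energy <- function(cyto, fields, params) {
  stopifnot(inherits(cyto, "cytoskeleton_state"),
            inherits(fields, "mechanical_fields"))
  if (cyto$conservation_residual > 1e-6) {
    stop("cytoskeleton state violates protein conservation", call. = FALSE)
  }
  p <- fields$points
  en <- cyto$eta * cyto$n_fib
  term <- matrix(0, nrow(en), ncol(en))
  pos <- en > 1e-300
  emq <- matrix(cyto$etamax_q, nrow(en), ncol(en))
  term[pos] <- en[pos] * (log(en[pos] / emq[pos]) - 1 - cyto$Psi[pos])
  bound <- sum(p$w * rowMeans(term)) / cyto$A_ref
  params$C_cyto * (cyto$N_u * (log(cyto$N_u) - 1) + bound) / params$E_norm
}

#' Substrate tractions and Helmholtz energy
#'
#' Computes the traction field the cell exerts on the substrate from
#' in-plane equilibrium of the total (passive + active fibre) Cauchy
#' stress: the interior divergence plus the free-edge stress resultant
#' transmitted through a peripheral adhesion band, projected to zero net
#' force and torque. On an elastic substrate the Winkler foundation
#' (modulus `k = winkler_c E_sub / R0`) stores
#' `F_sub = 1/(2 k E_norm) ∫ |T|^2 dA`; a rigid island stores nothing.
#'
#' @inheritParams gibbs
#' @return A list: `tractions` (tibble with deformed coordinates, `T1`,
#'   `T2`, `T_mag` in kPa), `F_sub`, `T_total` (normalized by
#'   `sigma_max pi R0^2`), and the net force/torque residuals.
#' @export
substrate_energy_and_tractions <- function(shape, env, params, ctx = NULL,
                                           sigma_max = NULL) {
  if (is.null(ctx)) ctx <- model_context(params, env)
  f <- .fields_eval_cpp(shape$coefficients, unclass(ctx),
                        params_vector(params, sigma_max))
  if (!isTRUE(f$valid)) {
    stop("invalid microstate: degenerate map or island confinement violated",
         call. = FALSE)
  }
  st <- f$stats
  list(
    tractions = tibble::tibble(
      x1 = drop(f$x1), x2 = drop(f$x2), J = drop(f$J),
      w = ctx$w, T1 = drop(f$T1), T2 = drop(f$T2),
      T_mag = sqrt(drop(f$T1)^2 + drop(f$T2)^2)),
    F_sub = st[["F_sub"]], T_total = st[["T_total"]],
    force_residual = st[["force_residual"]],
    torque_residual = st[["torque_residual"]])
}

#' Winkler foundation energy of a uniform traction patch
#'
#' Closed form `|T|^2 A / (2 k E_norm)` for a patch of area `A` carrying
#' uniform traction magnitude `|T|` on a Winkler foundation of modulus
#' `k`; the elementary building block of the substrate energy.
#'
#' @param T_mag Traction magnitude, kPa.
#' @param area Patch area, um^2.
#' @param k Foundation modulus, kPa/um.
#' @param E_norm Energy normalization, fJ.
#' @return Dimensionless energy.
#' @export
winkler_energy <- function(T_mag, area, k, E_norm = 1) {
  stopifnot(k > 0, E_norm > 0)
  T_mag^2 * area / (2 * k * E_norm)
}

#' Gibbs free energy of the suspended cell
#'
#' Solves the 1D radial balance of the isolated circular cell in
#' suspension: the isotropic tensile stress of the (isotropically
#' distributed) stress fibres is balanced by passive elastic compression,
#' `sigma_passive(lambda) + eta(lambda) sigma(lambda)/2 = 0`, for the
#' equibiaxial suspended stretch `lambda_s <= 1`. The suspension energy
#' `G_S = F_passive(lambda_s) + F_cyto(lambda_s)` is the reference value
#' of the homeostatic constraint `<G> = G_S`.
#'
#' @param params A [cell_parameters()] object.
#' @param sigma_max Optional override of the fibre tension ceiling, kPa.
#' @return A list: `G_S` (dimensionless), `lambda_s`, `N_u`, `N_b`, and
#'   an updated copy of `params` with `G_S` cached.
#' @examples
#' suspension_energy(cell_parameters())$lambda_s  # < 1: contracted
#' @export
suspension_energy <- function(params, sigma_max = NULL) {
  stopifnot(inherits(params, "cell_params"))
  smax <- if (is.null(sigma_max)) params$sigma_max else sigma_max
  sc <- params$E_susp / (params$E_susp + params$E_half)
  q <- disc_quadrature(params$R0)
  s <- smoothstep((q$r - params$RN) / max(params$interface_w, 1e-12))
  mu_q <- params$mu_n + (params$mu_c - params$mu_n) * s
  A_ref <- sum(q$w * s)
  m <- params$m

  uniform_state <- function(lam) {
    epsv <- lam - 1
    sig <- smax * sc * min(1, max(0, 1 + params$beta * epsv))
    Psi <- (sig * params$Omega - params$mu_b0) / params$kT_hat
    W <- exp(Psi)
    nf <- max(lam, params$n_min)
    g <- function(Nu) Nu + (Nu * W / (1 + Nu * W)) * params$eta_max * nf - 1
    Nu <- stats::uniroot(g, c(1e-12, 1), tol = 1e-14)$root
    frac <- Nu * W / (1 + Nu * W)
    list(eps = epsv, sig = sig, Psi = Psi, Nu = Nu, frac = frac, nf = nf)
  }
  balance <- function(lam) {
    st <- uniform_state(lam)
    J <- lam^2
    sig_pass <- (2 * params$mu_c / (m * J)) * (lam^m - 1) +
      params$kappa * (J - 1)
    sig_act <- params$rho_f * params$eta_max * st$frac * st$sig / 2
    sig_pass + sig_act
  }
  lambda_s <- if (smax == 0) 1 else {
    stats::uniroot(balance, c(0.2, 1), tol = 1e-12,
                   extendInt = "no")$root
  }
  st <- uniform_state(lambda_s)
  J <- lambda_s^2
  Fpass <- params$t0 * ((2 / m^2) * (2 * lambda_s^m - 2 - m * log(J)) *
                          sum(q$w * mu_q) +
                          params$kappa / 2 * (J - 1)^2 * sum(q$w)) /
    params$E_norm
  en <- params$eta_max * st$frac * st$nf
  bound <- if (en > 1e-300) en * (log(st$frac * st$nf) - 1 - st$Psi) else 0
  Fcyto <- params$C_cyto * (st$Nu * (log(st$Nu) - 1) + bound) / params$E_norm
  G_S <- Fpass + Fcyto
  params$G_S <- G_S
  list(G_S = G_S, lambda_s = lambda_s, N_u = st$Nu, N_b = 1 - st$Nu,
       F_passive = Fpass, F_cyto = Fcyto, params = params)
}

# params with G_S guaranteed present
ensure_GS <- function(params, sigma_max = NULL) {
  if (is.null(params$G_S) || !is.null(sigma_max)) {
    suspension_energy(params, sigma_max)$params
  } else {
    params
  }
}
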