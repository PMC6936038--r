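#' Cell material and biochemical parameters
#'
#' Bundles every constant of the single-cell model: the reference geometry
#' (cell radius `R0`, nucleus radius `RN`, thickness `t0`), the passive 2D
#' Ogden elasticity of cytoplasm and nucleus (`mu_c`, `mu_n`, exponent `m`,
#' areal bulk penalty `kappa`), the stress-fibre cytoskeleton closure
#' (`sigma_max`, strain sensitivity `beta`, binding volume `Omega`,
#' reference binding chemical potential `mu_b0`, normalized fluctuation
#' scale `kT_hat`, saturation concentration `eta_max`, functional-unit
#' floor `n_min`, energy scale `C_cyto`), the Winkler substrate constant
#' `winkler_c`, and the energy normalization `E_norm`.
#'
#' All reported free energies are dimensionless: energy (in fJ, i.e.
#' kPa um^3) divided by `E_norm`. The normalized Gibbs energy of the cell
#' in suspension, `G_S`, is computed lazily by [suspension_energy()] and
#' cached here.
#'
#' @param R0 Reference (elastic resting state) cell radius, um.
#' @param RN Nucleus radius, um; must satisfy `RN < R0`.
#' @param t0 Cell thickness used to convert 2D energy densities, um.
#' @param mu_c,mu_n Ogden shear-like moduli of cytoplasm and nucleus, kPa.
#' @param m Ogden exponent (dimensionless).
#' @param kappa Areal bulk penalty modulus, kPa.
#' @param sigma_max Maximum tensile stress a stress fibre generates, kPa.
#'   240 kPa for untreated hMSCs; ROCK inhibition is modelled as a
#'   reduction to 231 kPa.
#' @param beta Fibre tension strain sensitivity (dimensionless): the fibre
#'   tension is `sigma_max * clamp(1 + beta * eps, 0, 1)` - the isometric
#'   ceiling `sigma_max` for stretched fibres, falling linearly to zero
#'   under shortening.
#' @param Omega Normalized binding volume, 1/kPa: converts fibre tension
#'   into a binding advantage.
#' @param mu_b0 Normalized standard chemical potential of bound
#'   stress-fibre protein (dimensionless).
#' @param kT_hat Normalized fluctuation scale of the binding equilibrium
#'   (dimensionless).
#' @param eta_max Saturation value of the angular stress-fibre
#'   concentration (dimensionless).
#' @param rho_f Stress-fibre volume fraction scaling the active Cauchy
#'   stress the cytoskeleton transmits (dimensionless).
#' @param E_half Substrate stiffness at which the effective fibre stall
#'   tension reaches half its ceiling, kPa: on an elastic substrate the
#'   tension ceiling is `sigma_max * E_sub/(E_sub + E_half)` (fibres
#'   pulling on a compliant anchor stall at lower tension); rigid
#'   islands give the full `sigma_max`.
#' @param E_susp Effective anchor stiffness of the suspended cell, kPa
#'   (fibres in suspension anchor against the cell's own cortex).
#' @param n_min Lower clip for the number of functional units per fibre.
#' @param C_cyto Energy scale of the cytoskeletal free energy, fJ.
#' @param E_norm Energy normalization scale, fJ; all reported energies are
#'   energy / `E_norm`.
#' @param winkler_c Dimensionless Winkler constant: the foundation modulus
#'   is `k = winkler_c * E_sub / R0` (kPa/um).
#' @param interface_w Smoothing width of the nucleus/cytoplasm interface
#'   used by the traction model, um.
#' @param edge_w Width of the peripheral adhesion band over which the
#'   free-edge stress resultant is transmitted to the substrate, um.
#' @param G_S Normalized suspension Gibbs energy; computed by
#'   [suspension_energy()] when `NULL`.
#'
#' @return An object of class `cell_params` (a named list).
#' @examples
#' p <- cell_parameters()
#' p$R0
#' @export
cell_parameters <- function(R0 = 20, RN = 6, t0 = 1,
                            mu_c = 1, mu_n = 8, m = 2, kappa = 1,
                            sigma_max = 240, beta = 3,
                            Omega = 0.01, mu_b0 = 1.3, kT_hat = 1,
                            eta_max = 1.5, n_min = 0.5, rho_f = 0.05,
                            E_half = 3, E_susp = 0.7,
                            C_cyto = 6000, E_norm = 1000,
                            winkler_c = 2.5, interface_w = 2, edge_w = 2,
                            G_S = NULL) {
  stopifnot(R0 > 0, RN > 0, RN < R0, t0 > 0,
            mu_c > 0, mu_n > 0, m > 0, kappa > 0,
            sigma_max >= 0, beta >= 0, Omega > 0, kT_hat > 0,
            eta_max > 0, n_min > 0, rho_f > 0, E_half > 0, E_susp > 0,
            C_cyto > 0, E_norm > 0,
            winkler_c > 0, interface_w >= 0, edge_w > 0)
  structure(
    list(R0 = R0, RN = RN, t0 = t0,
         mu_c = mu_c, mu_n = mu_n, m = m, kappa = kappa,
         sigma_max = sigma_max, beta = beta,
         Omega = Omega, mu_b0 = mu_b0, kT_hat = kT_hat,
         eta_max = eta_max, n_min = n_min, rho_f = rho_f,
         E_half = E_half, E_susp = E_susp,
         C_cyto = C_cyto, E_norm = E_norm,
         winkler_c = winkler_c, interface_w = interface_w, edge_w = edge_w,
         G_S = G_S),
    class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>\n")
  cat(sprintf("  geometry : R0 = %g um, RN = %g um, t0 = %g um\n",
              x$R0, x$RN, x$t0))
  cat(sprintf("  passive  : mu_c = %g kPa, mu_n = %g kPa, m = %g, kappa = %g kPa\n",
              x$mu_c, x$mu_n, x$m, x$kappa))
  cat(sprintf("  fibres   : sigma_max = %g kPa, beta = %g, Omega = %g /kPa, mu_b0 = %g\n",
              x$sigma_max, x$beta, x$Omega, x$mu_b0))
  cat(sprintf("  energy   : C_cyto = %g fJ, E_norm = %g fJ, G_S = %s\n",
              x$C_cyto, x$E_norm,
              if (is.null(x$G_S)) "<not yet computed>" else format(x$G_S)))
  invisible(x)
}

#' Substrate environments
#'
#' `env_elastic()` describes a uniform linear elastic substrate of
#' stiffness `E_sub` (kPa), modelled as a Winkler foundation with modulus
#' `k = winkler_c * E_sub / R0`. `env_island()` describes a square
#' adhesive island of area `A_p` (um^2), centred at the origin, patterned
#' on an effectively rigid substrate: the cell footprint must stay inside
#' the island and the rigid substrate stores no elastic energy.
#'
#' @param E_sub Substrate stiffness, kPa (must be > 0).
#' @param A_p Island area, um^2 (must be > 0).
#' @param nu_sub Substrate Poisson ratio (kept for provenance; the Winkler
#'   foundation does not use it).
#' @return An object of class `cell_env`.
#' @examples
#' env_elastic(30)
#' env_island(2025)
#' @export
env_elastic <- function(E_sub, nu_sub = 0.45) {
  stopifnot(is.numeric(E_sub), length(E_sub) == 1, E_sub > 0)
  structure(list(kind = "elastic_uniform", E_sub = E_sub, A_p = NA_real_,
                 nu_sub = nu_sub),
            class = "cell_env")
}

#' @rdname env_elastic
#' @export
env_island <- function(A_p, nu_sub = 0.45) {
  stopifnot(is.numeric(A_p), length(A_p) == 1, A_p > 0)
  structure(list(kind = "rigid_island", E_sub = Inf, A_p = A_p,
                 nu_sub = nu_sub),
            class = "cell_env")
}

#' @export
print.cell_env <- function(x, ...) {
  if (x$kind == "elastic_uniform") {
    cat(sprintf("<cell_env> elastic substrate, E_sub = %g kPa\n", x$E_sub))
  } else {
    cat(sprintf("<cell_env> rigid square adhesive island, A_p = %g um^2 (side %.2f um)\n",
                x$A_p, sqrt(x$A_p)))
  }
  invisible(x)
}

# short fingerprint of a params/env pair for provenance columns
config_fingerprint <- function(params, env) {
  s <- paste(
    vapply(params[setdiff(names(params), "G_S")], function(v) format(v, digits = 12), ""),
    collapse = ",")
  e <- paste(env$kind, format(env$E_sub), format(env$A_p), sep = ",")
  sprintf("%08x", sum(utf8ToInt(paste(s, e)) * seq_len(nchar(paste(s, e)))) %% 0xFFFFFFF)
}
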