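# Shape basis, disc quadrature and the precomputed model context consumed
# by the compiled energy kernel. The basis is defined once, here; C++ only
# sees numeric matrices.
#
# A morphological microstate is a smooth map x = chi(X) of the reference
# circle (radius R0). chi = identity + affine part (4 coefficients) +
# r-weighted polar harmonics up to order 4 (16 coefficients), K = 20:
#   u_r     = R0 (r/R0)^n (a_n cos n.th + b_n sin n.th)
#   u_theta = R0 (r/R0)^n (c_n cos n.th + d_n sin n.th),  n = 1..4
# The (r/R0)^n radial weight keeps the map smooth at the origin.

SHAPE_K <- 20L
HARMONIC_ORDERS <- 1:4

#' Shape state: coefficients of one morphological microstate
#'
#' A thin record holding the `K = 20` coefficients of the deformation map
#' (4 affine + 16 polar-harmonic), plus provenance (seed and chain step).
#' `coefficients = rep(0, 20)` is the identity map (the elastic resting
#' state).
#'
#' @param coefficients Numeric vector of length 20 (affine deviations
#'   `A11-1, A12, A21, A22-1`, then for each harmonic order n = 1..4 the
#'   radial-cos, radial-sin, tangential-cos, tangential-sin amplitudes).
#' @param seed,step Optional provenance integers.
#' @return An object of class `shape_state`.
#' @examples
#' shape_state()            # identity map
#' shape_state(c(0.2, 0, 0, 0.2, rep(0, 16)))  # uniform 1.2x dilation
#' @export
shape_state <- function(coefficients = rep(0, SHAPE_K), seed = NA_integer_,
                        step = NA_integer_) {
  coefficients <- as.numeric(coefficients)
  stopifnot(length(coefficients) == SHAPE_K, all(is.finite(coefficients)))
  structure(list(coefficients = coefficients, seed = seed, step = step),
            class = "shape_state")
}

#' @export
print.shape_state <- function(x, ...) {
  cat("<shape_state> K =", length(x$coefficients),
      "coefficients; max |c| =", format(max(abs(x$coefficients)), digits = 3), "\n")
  invisible(x)
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = (2 * e$vectors[1, idx]^2))
}

# polynomial differentiation matrix at nodes x (barycentric)
poly_diff_matrix <- function(x) {
  n <- length(x)
  w <- vapply(seq_len(n), function(j) 1 / prod(x[j] - x[-j]), 0)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) D[i, j] <- (w[j] / w[i]) / (x[i] - x[j])
  }
  diag(D) <- -rowSums(D)
  D
}

# Fourier differentiation matrix for an even number of equispaced points
fourier_diff_matrix <- function(n) {
  stopifnot(n %% 2 == 0)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      k <- i - j
      D[i, j] <- 0.5 * (-1)^k / tan(k * pi / n)
    }
  }
  D
}

# tensor quadrature over the reference disc: nr Gauss-Legendre radial
# nodes x nth equispaced angles. Ordering: radial index fastest, so a
# length nr*nth field reshapes to an nr x nth matrix column-by-column.
disc_quadrature <- function(R0, nr = 24L, nth = 36L) {
  gl <- gauss_legendre(nr)
  rn <- R0 * (gl$x + 1) / 2            # nodes on (0, R0)
  wr <- gl$w * R0 / 2                  # radial weights (dr)
  th <- 2 * pi * (seq_len(nth) - 1) / nth
  wt <- rep(2 * pi / nth, nth)
  r <- rep(rn, times = nth)
  theta <- rep(th, each = nr)
  w <- rep(wr * rn, times = nth) * rep(wt, each = nr)  # r dr dtheta
  list(r = r, theta = theta, w = w, r_nodes = rn, th_nodes = th,
       nr = nr, nth = nth)
}

# Displacement basis P (positions): two (npts x K) matrices such that
# x1 = X1 + P1 %*% c, x2 = X2 + P2 %*% c.
shape_basis_position <- function(r, theta, R0) {
  n_pts <- length(r)
  P1 <- matrix(0, n_pts, SHAPE_K)
  P2 <- matrix(0, n_pts, SHAPE_K)
  ct <- cos(theta); st <- sin(theta)
  X1 <- r * ct; X2 <- r * st
  P1[, 1] <- X1; P1[, 2] <- X2
  P2[, 3] <- X1; P2[, 4] <- X2
  for (n in HARMONIC_ORDERS) {
    f <- R0 * (r / R0)^n
    cn <- cos(n * theta); sn <- sin(n * theta)
    base <- 4L + (n - 1L) * 4L
    # radial-cos, radial-sin: u = f * g(theta) e_r
    P1[, base + 1L] <- f * cn * ct; P2[, base + 1L] <- f * cn * st
    P1[, base + 2L] <- f * sn * ct; P2[, base + 2L] <- f * sn * st
    # tangential-cos, tangential-sin: u = f * h(theta) e_theta
    P1[, base + 3L] <- -f * cn * st; P2[, base + 3L] <- f * cn * ct
    P1[, base + 4L] <- -f * sn * st; P2[, base + 4L] <- f * sn * ct
  }
  list(P1 = P1, P2 = P2)
}

# Displacement-gradient basis: four (npts x K) matrices G11..G22 with
# F = I + [G11 c, G12 c; G21 c, G22 c] (Cartesian components).
shape_basis_gradient <- function(r, theta, R0) {
  n_pts <- length(r)
  G11 <- matrix(0, n_pts, SHAPE_K); G12 <- matrix(0, n_pts, SHAPE_K)
  G21 <- matrix(0, n_pts, SHAPE_K); G22 <- matrix(0, n_pts, SHAPE_K)
  G11[, 1] <- 1; G12[, 2] <- 1; G21[, 3] <- 1; G22[, 4] <- 1
  ct <- cos(theta); st <- sin(theta)
  rot <- function(h11, h12, h21, h22) {
    # Q H Q^t with Q = [ct -st; st ct]
    list(
      h11 = ct^2 * h11 - ct * st * (h12 + h21) + st^2 * h22,
      h12 = ct * st * h11 + ct^2 * h12 - st^2 * h21 - ct * st * h22,
      h21 = ct * st * h11 - st^2 * h12 + ct^2 * h21 - ct * st * h22,
      h22 = st^2 * h11 + ct * st * (h12 + h21) + ct^2 * h22)
  }
  for (n in HARMONIC_ORDERS) {
    fp <- n * (r / R0)^(n - 1)      # d/dr of R0 (r/R0)^n
    fr <- (r / R0)^(n - 1)          # f / r
    cn <- cos(n * theta); sn <- sin(n * theta)
    base <- 4L + (n - 1L) * 4L
    modes <- list(
      list(idx = base + 1L, g = cn, gp = -n * sn, h = 0,  hp = 0),
      list(idx = base + 2L, g = sn, gp =  n * cn, h = 0,  hp = 0),
      list(idx = base + 3L, g = 0,  gp = 0,       h = cn, hp = -n * sn),
      list(idx = base + 4L, g = 0,  gp = 0,       h = sn, hp =  n * cn))
    for (mo in modes) {
      # polar gradient of u = f g e_r + f h e_th
      h11 <- fp * mo$g                    # du_r/dr
      h12 <- fr * (mo$gp - mo$h)          # (du_r/dth - u_th)/r
      h21 <- fp * mo$h                    # du_th/dr
      h22 <- fr * (mo$hp + mo$g)          # (du_th/dth + u_r)/r
      cc <- rot(h11, h12, h21, h22)
      G11[, mo$idx] <- cc$h11; G12[, mo$idx] <- cc$h12
      G21[, mo$idx] <- cc$h21; G22[, mo$idx] <- cc$h22
    }
  }
  list(G11 = G11, G12 = G12, G21 = G21, G22 = G22)
}

# smoothstep from 0 (t <= 0) to 1 (t >= 1)
smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

#' Precomputed model context
#'
#' Assembles the quadrature grid, shape-basis matrices, spectral
#' differentiation matrices and smoothed material fields consumed by the
#' compiled Gibbs-energy kernel. Users normally never call this directly;
#' [gibbs()], [metropolis_chain()] and friends build it on demand.
#'
#' @param params A [cell_parameters()] object.
#' @param env A [env_elastic()] or [env_island()] environment.
#' @param nr,nth Radial x angular quadrature resolution on the reference
#'   disc (defaults 24 x 36).
#' @param nphi Number of fibre orientation bins on `[0, pi)` (default 24).
#' @param nb Number of boundary points used for island confinement and
#'   footprint-simplicity checks.
#' @return A list (class `model_context`) of numeric arrays.
#' @keywords internal
#' @export
model_context <- function(params, env, nr = 24L, nth = 36L, nphi = 24L,
                          nb = 72L) {
  stopifnot(inherits(params, "cell_params"), inherits(env, "cell_env"))
  R0 <- params$R0
  q <- disc_quadrature(R0, nr, nth)
  pos <- shape_basis_position(q$r, q$theta, R0)
  grd <- shape_basis_gradient(q$r, q$theta, R0)

  # smoothed nucleus -> cytoplasm transition (traction model needs a
  # continuous modulus; fibres are excluded from the nucleus)
  w_int <- params$interface_w
  s <- if (w_int > 0) smoothstep((q$r - params$RN) / w_int) else
    as.numeric(q$r >= params$RN)
  mu_q <- params$mu_n + (params$mu_c - params$mu_n) * s
  mask_q <- s                                  # fibre availability in [0,1]
  etamax_q <- params$eta_max * mask_q
  A_ref <- sum(q$w * mask_q)                   # reference cytoplasm measure

  # peripheral adhesion band weight for the free-edge stress resultant:
  # per angular column, a radial weight g(r) supported on (R0-edge_w, R0),
  # normalized so that sum_r wq g = 1 within each column.
  g_edge <- smoothstep((q$r - (R0 - params$edge_w)) / params$edge_w)
  # the kernel normalizes g_edge per angular column against the deformed
  # area measure, so the distributed band force equals the edge resultant

  phi <- (seq_len(nphi) - 0.5) * pi / nphi
  th_b <- 2 * pi * (seq_len(nb) - 1) / nb
  pb <- shape_basis_position(rep(R0, nb), th_b, R0)

  # boundary tangent basis (d/dtheta of positions at r = R0) for the
  # spectral boundary area integral
  eps_th <- 1e-6
  pb_p <- shape_basis_position(rep(R0, nb), th_b + eps_th, R0)
  pb_m <- shape_basis_position(rep(R0, nb), th_b - eps_th, R0)
  Db1 <- (pb_p$P1 - pb_m$P1) / (2 * eps_th)
  Db2 <- (pb_p$P2 - pb_m$P2) / (2 * eps_th)

  ctx <- list(
    nr = nr, nth = nth, nphi = nphi, nb = nb, K = SHAPE_K,
    r = q$r, theta = q$theta, w = q$w,
    X1 = q$r * cos(q$theta), X2 = q$r * sin(q$theta),
    P1 = pos$P1, P2 = pos$P2,
    G11 = grd$G11, G12 = grd$G12, G21 = grd$G21, G22 = grd$G22,
    Dr = poly_diff_matrix(q$r_nodes), Dth = fourier_diff_matrix(nth),
    cphi = cos(phi), sphi = sin(phi), phi = phi,
    mu_q = mu_q, etamax_q = etamax_q, mask_q = mask_q, A_ref = A_ref,
    region = as.integer(q$r < params$RN),
    g_edge = g_edge,
    Xb1 = R0 * cos(th_b), Xb2 = R0 * sin(th_b),
    Pb1 = pb$P1, Pb2 = pb$P2, Db1 = Db1, Db2 = Db2,
    dXb1 = -R0 * sin(th_b), dXb2 = R0 * cos(th_b), th_b = th_b,
    # environment
    kind = if (env$kind == "elastic_uniform") 0L else 1L,
    sig_scale = if (env$kind == "elastic_uniform")
      env$E_sub / (env$E_sub + params$E_half) else 1,
    k_w = if (env$kind == "elastic_uniform")
      params$winkler_c * env$E_sub / R0 else 0,
    half_side = if (env$kind == "rigid_island") sqrt(env$A_p) / 2 else Inf)
  class(ctx) <- "model_context"
  ctx
}

# flatten the scalar parameters for the C++ kernel
params_vector <- function(params, sigma_max = NULL) {
  c(R0 = params$R0, RN = params$RN, t0 = params$t0,
    m = params$m, kappa = params$kappa,
    sigma_max = if (is.null(sigma_max)) params$sigma_max else sigma_max,
    beta = params$beta, Omega = params$Omega, mu_b0 = params$mu_b0,
    kT_hat = params$kT_hat, n_min = params$n_min, rho_f = params$rho_f,
    C_cyto = params$C_cyto, E_norm = params$E_norm)
}
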