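#' Reference (elastic resting) cell
#'
#' The undeformed microstate: the identity map, whose footprint is the
#' circle of radius `R0` with the nucleus circle of radius `RN` at its
#' centre. Every strain measure vanishes here and the passive elastic
#' energy is exactly zero.
#'
#' @param params A [cell_parameters()] object.
#' @return A [shape_state()] with zero coefficients.
#' @examples
#' make_reference_cell(cell_parameters())
#' @export
make_reference_cell <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  shape_state(rep(0, SHAPE_K))
}

#' Kinematic fields of a morphological microstate
#'
#' Evaluates, on the fixed tensor quadrature grid over the reference
#' disc, the deformation gradient `F`, the areal stretch `J = det F`, the
#' principal in-plane stretches, and the nominal strain `eps(phi)` of the
#' unit material fibre at each of `nphi` orientations (the stretch of the
#' material direction at angle `phi`, minus one).
#'
#' @param shape A [shape_state()].
#' @param params A [cell_parameters()] object.
#' @param nr,nth,nphi Grid resolution (defaults match the energy kernel).
#' @return A list of class `mechanical_fields`: `points` (a tibble with
#'   one row per quadrature point: reference and deformed coordinates,
#'   the four components of `F`, `J`, `lambda_I`, `lambda_II`, region
#'   label and quadrature weight), `eps` (matrix, points x orientations),
#'   `phi` (orientation angles), and the resolution.
#' @examples
#' p <- cell_parameters()
#' mf <- evaluate_kinematics(make_reference_cell(p), p)
#' range(mf$points$J)  # identically 1
#' @export
evaluate_kinematics <- function(shape, params, nr = 24L, nth = 36L,
                                nphi = 24L) {
  stopifnot(inherits(shape, "shape_state"), inherits(params, "cell_params"))
  cvec <- shape$coefficients
  q <- disc_quadrature(params$R0, nr, nth)
  grd <- shape_basis_gradient(q$r, q$theta, params$R0)
  pos <- shape_basis_position(q$r, q$theta, params$R0)
  F11 <- 1 + drop(grd$G11 %*% cvec); F12 <- drop(grd$G12 %*% cvec)
  F21 <- drop(grd$G21 %*% cvec);     F22 <- 1 + drop(grd$G22 %*% cvec)
  J <- F11 * F22 - F12 * F21
  if (min(J) <= 0) {
    stop("invalid microstate: the deformation map is not orientation-preserving (det F <= 0 on the grid)",
         call. = FALSE)
  }
  C11 <- F11^2 + F21^2; C12 <- F11 * F12 + F21 * F22; C22 <- F12^2 + F22^2
  tr <- (C11 + C22) / 2
  disc <- sqrt(pmax(0, ((C11 - C22) / 2)^2 + C12^2))
  lambda_I <- sqrt(tr + disc)
  lambda_II <- sqrt(pmax(tr - disc, 0))
  phi <- (seq_len(nphi) - 0.5) * pi / nphi
  eps <- sqrt(outer(C11, cos(phi)^2) + outer(C12, 2 * cos(phi) * sin(phi)) +
                outer(C22, sin(phi)^2)) - 1
  X1 <- q$r * cos(q$theta); X2 <- q$r * sin(q$theta)
  pts <- tibble::tibble(
    r = q$r, theta = q$theta, w = q$w, X1 = X1, X2 = X2,
    x1 = X1 + drop(pos$P1 %*% cvec), x2 = X2 + drop(pos$P2 %*% cvec),
    F11 = F11, F12 = F12, F21 = F21, F22 = F22, J = J,
    lambda_I = lambda_I, lambda_II = lambda_II,
    region = ifelse(q$r < params$RN, "nucleus", "cytoplasm"))
  structure(list(points = pts, eps = eps, phi = phi,
                 nr = nr, nth = nth, nphi = nphi),
            class = "mechanical_fields")
}

#' @export
print.mechanical_fields <- function(x, ...) {
  cat(sprintf("<mechanical_fields> %d quadrature points, %d fibre orientations\n",
              nrow(x$points), length(x$phi)))
  cat(sprintf("  J in [%.4g, %.4g]; max |eps| = %.4g\n",
              min(x$points$J), max(x$points$J), max(abs(x$eps))))
  invisible(x)
}

# deformed boundary polygon (closed, counter-clockwise), n points
footprint_boundary <- function(shape, params, n = 256L, radius = NULL) {
  R0 <- params$R0
  rr <- if (is.null(radius)) R0 else radius
  th <- 2 * pi * (seq_len(n) - 1) / n
  pos <- shape_basis_position(rep(rr, n), th, R0)
  cvec <- shape$coefficients
  tibble::tibble(
    theta = th,
    x1 = rr * cos(th) + drop(pos$P1 %*% cvec),
    x2 = rr * sin(th) + drop(pos$P2 %*% cvec))
}

#' Footprint geometry of a microstate
#'
#' `footprint_area()` computes the deformed cell area either by the
#' spectral boundary integral `A = 1/2 ∮ (x1 dx2 - x2 dx1)` (exact to
#' machine precision for smooth maps) or by quadrature of the areal
#' stretch `∫ J dA` over the reference disc. `footprint_moments()`
#' returns the centroid, the central second area moments, and the aspect
#' ratio of the moment-equivalent (best-fit) ellipse.
#'
#' @param shape A [shape_state()].
#' @param params A [cell_parameters()] object.
#' @param method `"boundary"` or `"quadrature"`.
#' @param n Number of boundary points (boundary method).
#' @param radius Boundary radius in the reference configuration; default
#'   the cell radius `R0` (use `RN` for the nucleus outline).
#' @return `footprint_area()`: a single number (um^2);
#'   `footprint_moments()`: a one-row tibble.
#' @examples
#' p <- cell_parameters()
#' footprint_area(make_reference_cell(p), p)  # pi * R0^2
#' @export
footprint_area <- function(shape, params, method = c("boundary", "quadrature"),
                           n = 256L, radius = NULL) {
  method <- match.arg(method)
  if (method == "boundary") {
    R0 <- params$R0
    rr <- if (is.null(radius)) R0 else radius
    th <- 2 * pi * (seq_len(n) - 1) / n
    pos <- shape_basis_position(rep(rr, n), th, R0)
    h <- 1e-6
    pp <- shape_basis_position(rep(rr, n), th + h, R0)
    pm <- shape_basis_position(rep(rr, n), th - h, R0)
    cvec <- shape$coefficients
    x1 <- rr * cos(th) + drop(pos$P1 %*% cvec)
    x2 <- rr * sin(th) + drop(pos$P2 %*% cvec)
    d1 <- -rr * sin(th) + drop((pp$P1 - pm$P1) %*% cvec) / (2 * h)
    d2 <- rr * cos(th) + drop((pp$P2 - pm$P2) %*% cvec) / (2 * h)
    sum(x1 * d2 - x2 * d1) / 2 * (2 * pi / n)
  } else {
    mf <- evaluate_kinematics(shape, params)
    if (!is.null(radius)) {
      keep <- mf$points$r < radius
      sum(mf$points$w[keep] * mf$points$J[keep])
    } else {
      sum(mf$points$w * mf$points$J)
    }
  }
}

#' @rdname footprint_area
#' @export
footprint_moments <- function(shape, params) {
  mf <- evaluate_kinematics(shape, params)
  wJ <- mf$points$w * mf$points$J
  A <- sum(wJ)
  cx <- sum(wJ * mf$points$x1) / A
  cy <- sum(wJ * mf$points$x2) / A
  Ixx <- sum(wJ * (mf$points$x1 - cx)^2) / A
  Iyy <- sum(wJ * (mf$points$x2 - cy)^2) / A
  Ixy <- sum(wJ * (mf$points$x1 - cx) * (mf$points$x2 - cy)) / A
  ev <- eigen(matrix(c(Ixx, Ixy, Ixy, Iyy), 2, 2), symmetric = TRUE)$values
  tibble::tibble(area = A, cx = cx, cy = cy, Ixx = Ixx, Ixy = Ixy,
                 Iyy = Iyy, aspect_ratio = sqrt(ev[1] / max(ev[2], 1e-300)))
}

#' Island confinement check
#'
#' `TRUE` iff every boundary point of the deformed footprint lies inside
#' the closed square adhesive island (side `sqrt(A_p)`, centred at the
#' origin).
#'
#' @param shape A [shape_state()].
#' @param env An [env_island()] environment.
#' @param params A [cell_parameters()] object.
#' @param n Number of boundary points checked.
#' @return Logical scalar.
#' @examples
#' p <- cell_parameters(R0 = 20)
#' footprint_inside_island(make_reference_cell(p), env_island(2025), p)
#' @export
footprint_inside_island <- function(shape, env, params, n = 256L) {
  stopifnot(inherits(env, "cell_env"), env$kind == "rigid_island")
  b <- footprint_boundary(shape, params, n = n)
  hs <- sqrt(env$A_p) / 2
  all(abs(b$x1) <= hs & abs(b$x2) <= hs)
}
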