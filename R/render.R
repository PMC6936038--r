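# Immunofluorescence-like raster renders of a microstate: actin channel
# proportional to the orientation-integrated stress-fibre content, the
# adhesion channel proportional to normalized traction magnitude, and a
# nucleus mask; fixed micrometre-per-pixel scale with a scale bar.

# winding-number point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, bx, by) {
  n <- length(bx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((by[i] > py) != (by[j] > py)) &
      (px < (bx[j] - bx[i]) * (py - by[i]) / (by[j] - by[i]) + bx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# chunked nearest-neighbour lookup: index of the nearest (qx, qy) for
# each (px, py)
nearest_index <- function(px, py, qx, qy, chunk = 2000L) {
  out <- integer(length(px))
  for (s in seq(1, length(px), by = chunk)) {
    idx <- s:min(s + chunk - 1, length(px))
    d <- outer(px[idx], qx, "-")^2 + outer(py[idx], qy, "-")^2
    out[idx] <- max.col(-d, ties.method = "first")
  }
  out
}

#' Render a microstate as an immunofluorescence-like image
#'
#' Deterministic raster of one cell configuration at a fixed scale
#' (default 0.5 um/pixel): the actin channel is proportional to the
#' orientation-integrated stress-fibre content `∫ eta n dphi`, the
#' adhesion channel to the normalized traction magnitude `|T|/sigma_max`
#' (restricted, for islands, to the adhered footprint), and the nucleus
#' channel is the deformed nucleus mask. A 20 um scale bar is drawn in
#' the lower-left corner.
#'
#' @param shape A [shape_state()] (or one row of an ensemble; see
#'   [ensemble_shape()]).
#' @param env Environment.
#' @param params A [cell_parameters()] object.
#' @param style One of `"combined"`, `"actin"`, `"adhesions"`,
#'   `"nucleus"`.
#' @param um_per_px Pixel scale, um.
#' @param pad Margin around the footprint, um.
#' @param file Optional PNG path; when given, the image is written with
#'   [png::writePNG()] and the path returned invisibly.
#' @param colours Named list of RGB triplets for `actin`, `adhesions`,
#'   `nucleus` (cosmetic).
#' @return An `height x width x 3` RGB array in `[0, 1]` (invisibly the
#'   file path when `file` is given).
#' @export
render_cell <- function(shape, env, params,
                        style = c("combined", "actin", "adhesions",
                                  "nucleus"),
                        um_per_px = 0.5, pad = 5, file = NULL,
                        colours = list(actin = c(0, 1, 0),
                                       adhesions = c(1, 0.3, 0.8),
                                       nucleus = c(0.2, 0.3, 1))) {
  style <- match.arg(style)
  f <- .fields_eval_cpp(shape$coefficients,
                        unclass(model_context(params, env)),
                        params_vector(params))
  if (!isTRUE(f$valid)) stop("invalid microstate", call. = FALSE)
  bnd <- footprint_boundary(shape, params, n = 256L)
  nuc <- footprint_boundary(shape, params, n = 128L, radius = params$RN)

  half <- if (env$kind == "rigid_island") {
    max(sqrt(env$A_p) / 2, max(abs(c(bnd$x1, bnd$x2)))) + pad
  } else {
    max(abs(c(bnd$x1, bnd$x2))) + pad
  }
  nx <- 2L * as.integer(ceiling(half / um_per_px))
  xs <- (seq_len(nx) - 0.5) * um_per_px - half
  gx <- rep(xs, times = nx); gy <- rep(xs, each = nx)

  inside <- points_in_polygon(gx, gy, bnd$x1, bnd$x2)
  in_nuc <- points_in_polygon(gx, gy, nuc$x1, nuc$x2)

  sf_q <- rowMeans(f$eta * f$n_fib)          # per-point fibre content
  tq <- sqrt(drop(f$T1)^2 + drop(f$T2)^2) /
    max(params$sigma_max, .Machine$double.eps)
  qx <- drop(f$x1); qy <- drop(f$x2)

  actin <- adhes <- numeric(length(gx))
  if (any(inside)) {
    ni <- nearest_index(gx[inside], gy[inside], qx, qy)
    actin[inside] <- sf_q[ni]
    adhes[inside] <- tq[ni]
  }
  if (env$kind == "rigid_island") {
    hs <- sqrt(env$A_p) / 2
    adhes[abs(gx) > hs | abs(gy) > hs] <- 0
  }
  norm01 <- function(v) if (max(v) > 0) v / max(v) else v
  actin <- norm01(actin); adhes <- norm01(adhes)
  nucch <- as.numeric(in_nuc)

  img <- array(0, dim = c(nx, nx, 3))
  add_channel <- function(img, v, col) {
    for (k in 1:3) img[, , k] <- pmin(1, img[, , k] + matrix(v, nx, nx) * col[k])
    img
  }
  if (style %in% c("combined", "actin")) img <- add_channel(img, actin, colours$actin)
  if (style %in% c("combined", "adhesions")) img <- add_channel(img, adhes, colours$adhesions)
  if (style %in% c("combined", "nucleus")) img <- add_channel(img, nucch, colours$nucleus)

  # row 1 should be the top of the image (y decreasing): transpose/flip
  img <- aperm(img, c(2, 1, 3))[nx:1, , , drop = FALSE]

  # 20 um scale bar, lower-left
  bar_px <- round(20 / um_per_px)
  rows <- (nx - 9):(nx - 7); cols <- 8:(8 + bar_px - 1)
  img[rows, cols, ] <- 1

  if (!is.null(file)) {
    png::writePNG(img, target = file)
    return(invisible(file))
  }
  img
}

#' Extract one sampled shape from an ensemble
#'
#' @param ensemble A `homeostatic_ensemble`.
#' @param i Row index.
#' @return The [shape_state()] of sample `i`.
#' @export
ensemble_shape <- function(ensemble, i) {
  co <- attr(ensemble, "coefficients")
  stopifnot(!is.null(co), i >= 1, i <= nrow(co))
  shape_state(co[i, ], seed = attr(ensemble, "seed"),
              step = ensemble$step[i])
}
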