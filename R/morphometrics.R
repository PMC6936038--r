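# Morphometric observables, marginal and joint densities.

#' Observables of a single microstate
#'
#' Computes, for one shape in one environment, the standard reported
#' observables: normalized area `A_hat = area / (pi R0^2)`, aspect ratio
#' `A_s` of the moment-equivalent best-fit ellipse, normalized total
#' traction `T_total = (1/(sigma_max pi R0^2)) ∫ |T| dA`, stress-fibre
#' polymerization `N_b = 1 - N_u`, and the cytoskeletal free energy.
#'
#' @param shape A [shape_state()].
#' @param env Environment.
#' @param params A [cell_parameters()] object.
#' @param ctx Optional precomputed [model_context()].
#' @return A one-row tibble.
#' @examples
#' p <- cell_parameters()
#' compute_observables(make_reference_cell(p), env_elastic(70), p)
#' @export
compute_observables <- function(shape, env, params, ctx = NULL) {
  b <- gibbs(shape, env, params, ctx = ctx)
  tibble::tibble(
    A_hat = b$area / (pi * params$R0^2),
    aspect_ratio = b$aspect_ratio,
    T_total = b$T_total,
    N_b = b$N_b,
    F_cyto = b$F_cyto)
}

#' Marginal kernel density estimate
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth, evaluated on a
#' regular grid and normalized to integrate to one.
#'
#' @param values Numeric sample (>= 10 values).
#' @param grid Optional length-2 range or explicit grid vector.
#' @param n_grid Grid size.
#' @param bw Bandwidth (default Silverman).
#' @return A tibble with columns `x`, `y` and attribute `bw`.
#' @export
marginal_density <- function(values, grid = NULL, n_grid = 512, bw = NULL) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input", call. = FALSE)
  stopifnot(length(values) >= 10)
  s <- stats::sd(values)
  if (is.null(bw)) bw <- if (s > 0) stats::bw.nrd0(values) else
    1e-6 * max(1, abs(values[1]))
  rng <- if (is.null(grid)) range(values) + c(-3, 3) * bw
         else if (length(grid) == 2) grid else range(grid)
  xs <- if (!is.null(grid) && length(grid) > 2) as.numeric(grid) else
    seq(rng[1], rng[2], length.out = n_grid)
  d <- stats::density(values, bw = bw, from = min(xs), to = max(xs),
                      n = length(xs))
  tb <- tibble::tibble(x = d$x, y = d$y)
  attr(tb, "bw") <- bw
  tb
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' L1 distance between two sample densities
#'
#' Kernel density estimates of both samples on a shared grid, then the
#' trapezoid integral of the absolute difference (in `[0, 2]`). Used to
#' quantify how strongly a treatment shifts an observable's
#' distribution.
#'
#' @param a,b Numeric samples.
#' @param n_grid Grid size.
#' @return The L1 distance.
#' @export
density_l1 <- function(a, b, n_grid = 512) {
  bw <- mean(c(stats::bw.nrd0(a), stats::bw.nrd0(b)))
  # quantile-windowed grid: rare extreme outliers would otherwise
  # stretch the grid and destroy resolution where the mass lives
  qs <- stats::quantile(c(a, b), c(0.0005, 0.9995), names = FALSE)
  rng <- qs + c(-3, 3) * bw
  da <- stats::density(a, bw = bw, from = rng[1], to = rng[2], n = n_grid)
  db <- stats::density(b, bw = bw, from = rng[1], to = rng[2], n = n_grid)
  trapz(da$x, abs(da$y - db$y))
}

#' Joint kernel density and correlation summary
#'
#' 2D Gaussian-kernel density estimate of two observables plus Pearson
#' and Spearman correlations with bootstrap confidence intervals; the
#' quantitative form of "are these two observables correlated?".
#'
#' @param x,y Numeric samples of equal length (>= 100).
#' @param n_grid Grid size per axis.
#' @param n_boot Bootstrap replicates for the correlation CIs.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return A list of class `joint_density`: `grid_x`, `grid_y`, `z`
#'   (density matrix), `pearson`, `spearman`, their CIs, and the
#'   marginals implied by the 2D estimate.
#' @export
joint_density <- function(x, y, n_grid = 101, n_boot = 200, conf = 0.95,
                          seed = 1L) {
  if (length(x) != length(y)) stop("mismatched lengths", call. = FALSE)
  stopifnot(length(x) >= 100)
  h <- c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  lims <- c(range(x) + c(-1, 1) * h[1], range(y) + c(-1, 1) * h[2])
  kd <- MASS::kde2d(x, y, h = h, n = n_grid, lims = lims)
  set.seed(seed %% .Machine$integer.max)
  n <- length(x)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    c(stats::cor(x[idx], y[idx]),
      stats::cor(x[idx], y[idx], method = "spearman"))
  }, numeric(2))
  alpha <- (1 - conf) / 2
  structure(list(
    grid_x = kd$x, grid_y = kd$y, z = kd$z,
    pearson = stats::cor(x, y),
    spearman = stats::cor(x, y, method = "spearman"),
    pearson_ci = stats::quantile(boots[1, ], c(alpha, 1 - alpha),
                                 names = FALSE),
    spearman_ci = stats::quantile(boots[2, ], c(alpha, 1 - alpha),
                                  names = FALSE),
    marginal_x = tibble::tibble(
      x = kd$x, y = apply(kd$z, 1, function(r) trapz(kd$y, r))),
    marginal_y = tibble::tibble(
      x = kd$y, y = apply(kd$z, 2, function(cl) trapz(kd$x, cl)))),
    class = "joint_density")
}

#' @export
print.joint_density <- function(x, ...) {
  cat(sprintf("<joint_density> %dx%d grid; Pearson r = %.3f [%.3f, %.3f], Spearman rho = %.3f\n",
              length(x$grid_x), length(x$grid_y), x$pearson,
              x$pearson_ci[1], x$pearson_ci[2], x$spearman))
  invisible(x)
}
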