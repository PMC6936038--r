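# Lineage forecasting: CLT density of the time-averaged cytoskeletal
# free energy, band probabilities, normalization, and band calibration.

#' CLT density of the time-averaged cytoskeletal free energy
#'
#' Over the commitment window the cell visits `Nc` decorrelated
#' microstates, so the time average of `F_cyto` is Gaussian with mean
#' `mu` and variance `sigma^2 / Nc`, where `(mu, sigma)` are the
#' homeostatic-ensemble mean and standard deviation of `F_cyto`.
#'
#' @param mu Ensemble mean of `F_cyto`.
#' @param sigma Ensemble standard deviation (> 0).
#' @param Nc Number of decorrelated microstates (>= 1).
#' @return A function `f(x)` evaluating the density.
#' @examples
#' f <- fbar_density(2, 0.6, 15)
#' integrate(f, -Inf, Inf)$value  # 1
#' @export
fbar_density <- function(mu, sigma, Nc) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  stopifnot(Nc >= 1)
  s <- sigma / sqrt(Nc)
  function(x) stats::dnorm(x, mean = mu, sd = s)
}

#' Raw lineage band probability
#'
#' Probability that the time-averaged cytoskeletal free energy falls in
#' the band `centre ± half_width`:
#' `Px = Phi((centre + hw - mu) sqrt(Nc)/sigma) -
#'       Phi((centre - hw - mu) sqrt(Nc)/sigma)`.
#'
#' @inheritParams fbar_density
#' @param band A one-row band ([lineage_band()]) or list with `centre`
#'   and `half_width`.
#' @return The raw probability in `[0, 1]` (vectorized over `mu` and
#'   `sigma`).
#' @export
lineage_probability <- function(mu, sigma, Nc, band) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (is.null(band$centre) || is.null(band$half_width) ||
      band$half_width < 0) {
    stop("invalid band", call. = FALSE)
  }
  s <- sigma / sqrt(Nc)
  stats::pnorm((band$centre + band$half_width - mu) / s) -
    stats::pnorm((band$centre - band$half_width - mu) / s)
}

#' Normalize raw lineage probabilities
#'
#' `Z_L = max(1, sum(Px))`; normalized probabilities are `Px / Z_L` and
#' the undifferentiated fraction is `1 - sum(Px)/Z_L`, so all outcomes
#' (including non-differentiation) sum to one.
#'
#' @param raw Named numeric vector of raw band probabilities in `[0, 1]`.
#' @return A list: `Z_L`, `p` (normalized probabilities),
#'   `undifferentiated`.
#' @examples
#' normalize_lineages(c(osteoblast = 0.9, myoblast = 0.6))
#' @export
normalize_lineages <- function(raw) {
  raw <- unlist(raw)
  if (any(raw < 0 | raw > 1)) stop("raw probabilities must lie in [0, 1]",
                                   call. = FALSE)
  Z_L <- max(1, sum(raw))
  list(Z_L = Z_L, p = raw / Z_L, undifferentiated = 1 - sum(raw) / Z_L)
}

#' Forecast lineage commitment from a homeostatic ensemble
#'
#' Summarizes the ensemble's `F_cyto` distribution into `(mu, sigma)`,
#' applies the CLT band classifier for every lineage of the media model,
#' and normalizes. Monte-Carlo standard errors on each probability are
#' propagated from the standard errors of `mu` and `sigma` by the delta
#' method.
#'
#' @param ensemble A `homeostatic_ensemble` (or any data frame with an
#'   `F_cyto` column).
#' @param media A [media_model()].
#' @return A `fate_forecast` tibble: one row per lineage plus one for
#'   `undifferentiated`, with raw and normalized probabilities and
#'   standard errors; `mu`, `sigma`, `Z_L`, `Nc` as attributes.
#' @export
forecast <- function(ensemble, media) {
  stopifnot(inherits(media, "media_model"))
  if (!"F_cyto" %in% names(ensemble)) {
    stop("ensemble lacks an F_cyto column", call. = FALSE)
  }
  st <- ensemble_statistics(ensemble, "F_cyto")
  Nc <- attr(media, "Nc")
  raw <- vapply(seq_len(nrow(media)), function(i) {
    lineage_probability(st$mean, st$sd, Nc, media[i, ])
  }, 0)
  names(raw) <- media$lineage
  nz <- normalize_lineages(raw)

  # delta-method SE via numerical gradient in (mu, sigma)
  se_sigma <- st$sd * sqrt(st$tau / (2 * (nrow(ensemble) - 1)))
  se_raw <- vapply(seq_len(nrow(media)), function(i) {
    h_mu <- 1e-5 * max(1, abs(st$mean))
    h_s <- 1e-5 * st$sd
    dmu <- (lineage_probability(st$mean + h_mu, st$sd, Nc, media[i, ]) -
              lineage_probability(st$mean - h_mu, st$sd, Nc, media[i, ])) /
      (2 * h_mu)
    ds <- (lineage_probability(st$mean, st$sd + h_s, Nc, media[i, ]) -
             lineage_probability(st$mean, max(st$sd - h_s, 1e-12), Nc,
                                 media[i, ])) / (2 * h_s)
    sqrt((dmu * st$se_mean)^2 + (ds * se_sigma)^2)
  }, 0)

  tb <- tibble::tibble(
    lineage = c(media$lineage, "undifferentiated"),
    p_raw = c(raw, NA_real_),
    p = c(nz$p, nz$undifferentiated),
    se = c(se_raw / nz$Z_L, sqrt(sum((se_raw / nz$Z_L)^2))))
  attr(tb, "mu") <- st$mean
  attr(tb, "sigma") <- st$sd
  attr(tb, "se_mu") <- st$se_mean
  attr(tb, "Z_L") <- nz$Z_L
  attr(tb, "Nc") <- Nc
  attr(tb, "media") <- attr(media, "media")
  class(tb) <- c("fate_forecast", class(tb))
  tb
}

#' @export
print.fate_forecast <- function(x, ...) {
  cat(sprintf("<fate_forecast> media = %s, mu = %.4f, sigma = %.4f, Z_L = %.3f\n",
              attr(x, "media"), attr(x, "mu"), attr(x, "sigma"),
              attr(x, "Z_L")))
  NextMethod()
}

#' Calibrate lineage bands against observed fractions
#'
#' Least-squares fit of each lineage's `(centre, half_width)` to
#' observed differentiation fractions across conditions, given the
#' ensemble summaries `(mu, sigma)` of those conditions — the
#' calibrate-on-one-cue, predict-on-another workflow. Undetected
#' lineages are lumped into non-differentiation. The fit minimizes
#' `sum_c (Px(mu_c, sigma_c) - observed_c)^2` subject to
#' `half_width >= 0`, with a deterministic grid multistart.
#'
#' @param stats_df Tibble with columns `condition`, `mu`, `sigma` (one
#'   row per condition).
#' @param observed Tibble with columns `condition`, `lineage`,
#'   `fraction`.
#' @param Nc Number of decorrelated microstates.
#' @param media Name for the returned media model.
#' @return A [media_model()] with one fitted band per lineage; fit
#'   residuals in attribute `fit`.
#' @export
calibrate_bands <- function(stats_df, observed, Nc = 15L, media = "calibrated") {
  stopifnot(all(c("condition", "mu", "sigma") %in% names(stats_df)),
            all(c("condition", "lineage", "fraction") %in% names(observed)))
  lineages <- unique(observed$lineage)
  fits <- lapply(lineages, function(lg) {
    obs <- dplyr::inner_join(observed[observed$lineage == lg, ], stats_df,
                             by = "condition")
    if (nrow(obs) < 2) {
      stop(sprintf("lineage '%s': need >= 2 conditions to fit 2 band parameters", lg),
           call. = FALSE)
    }
    sse <- function(par) {
      hw <- exp(par[2])
      p <- lineage_probability(obs$mu, obs$sigma, Nc,
                               list(centre = par[1], half_width = hw))
      sum((p - obs$fraction)^2)
    }
    # deterministic multistart: centres spanning the observed mu range,
    # widths from sub-band to whole-range scales
    peak <- obs$condition[which.max(obs$fraction)]
    mu_pk <- obs$mu[obs$condition == peak][1]
    sig_pk <- obs$sigma[obs$condition == peak][1]
    f_pk <- max(obs$fraction)
    hw0 <- sig_pk / sqrt(Nc) * stats::qnorm((1 + min(f_pk, 0.999)) / 2)
    span <- max(diff(range(obs$mu)), 4 * hw0)
    centres <- unique(c(mu_pk, seq(min(obs$mu), max(obs$mu),
                                   length.out = 7)))
    widths <- unique(pmax(c(hw0, hw0 / 3, hw0 * 3, span / 8, span / 4,
                            span / 2), 1e-8))
    starts <- expand.grid(centre = centres, lhw = log(widths))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- stats::optim(c(starts$centre[i], starts$lhw[i]), sse,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # Nelder-Mead + BFGS polish of the best start
    best <- stats::optim(best$par, sse, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-15))
    best <- stats::optim(best$par, sse, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-16))
    tibble::tibble(lineage = lg, centre = best$par[1],
                   half_width = exp(best$par[2]), sse = best$value,
                   n_conditions = nrow(obs))
  })
  fit <- dplyr::bind_rows(fits)
  mm <- media_model(fit[, c("lineage", "centre", "half_width")],
                    Nc = Nc, media = media)
  attr(mm, "fit") <- fit
  mm
}
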