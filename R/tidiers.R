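# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a homeostatic ensemble
#'
#' One row per retained sample with the observable columns (the
#' ensemble already is a tibble; `tidy()` strips the attributes and
#' returns a plain tibble).
#'
#' @param x A `homeostatic_ensemble`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.homeostatic_ensemble <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "coefficients") <- NULL
  out
}

#' Glance at a homeostatic ensemble
#'
#' One-row summary: `zeta`, sample count, acceptance rate, homeostatic
#' constraint gap, autocorrelation time and split-chain Rhat of `G`.
#'
#' @param x A `homeostatic_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.homeostatic_ensemble <- function(x, ...) {
  d <- attr(x, "diagnostics")
  p <- attr(x, "params")
  tibble::tibble(
    zeta = attr(x, "zeta"), n_samples = nrow(x),
    n_steps = d$n_steps, acceptance_rate = d$acceptance_rate,
    mean_G = mean(x$G), G_S = p$G_S,
    constraint_gap = mean(x$G) - p$G_S,
    tau_G = d$tau_G, rhat_G = d$rhat_G,
    converged = isTRUE(d$converged))
}

#' Tidy a fate forecast
#'
#' @param x A `fate_forecast`.
#' @param ... Unused.
#' @return A tibble with one row per outcome (lineages plus
#'   undifferentiated).
#' @export
tidy.fate_forecast <- function(x, ...) tibble::as_tibble(x)

#' Glance at a fate forecast
#'
#' @param x A `fate_forecast`.
#' @param ... Unused.
#' @return A one-row tibble with `mu`, `sigma`, `Z_L`, `Nc` and the
#'   undifferentiated fraction.
#' @export
glance.fate_forecast <- function(x, ...) {
  tibble::tibble(
    media = attr(x, "media"), mu = attr(x, "mu"), sigma = attr(x, "sigma"),
    Z_L = attr(x, "Z_L"), Nc = attr(x, "Nc"),
    undifferentiated = x$p[x$lineage == "undifferentiated"])
}
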