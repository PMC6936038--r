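# Enumerable toy state spaces: exact oracles for the sampler and the
# zeta solver, and HomeostaticEnsemble-compatible fixtures for the
# forecasting pipeline.

#' Toy enumerable microstate space
#'
#' An explicit finite list of microstates with assigned normalized Gibbs
#' energies (and optionally cytoskeletal free energies), for which the
#' equilibrium distribution, partition function and homeostatic `zeta`
#' are all computable by direct summation. Used as exact oracles for the
#' Metropolis machinery.
#'
#' @param G Numeric vector of state Gibbs energies.
#' @param F_cyto Optional cytoskeletal free energies (defaults to `G`).
#' @param G_S Target homeostatic mean (defaults to `mean(G)`).
#' @return An object of class `toy_ensemble_spec`.
#' @examples
#' toy <- toy_ensemble_spec(c(0, 1, 2), G_S = 0.8)
#' toy_peq(toy, zeta = 0.31)
#' @export
toy_ensemble_spec <- function(G, F_cyto = G, G_S = mean(G)) {
  G <- as.numeric(G)
  if (!length(G)) stop("toy state list must be non-empty", call. = FALSE)
  stopifnot(all(is.finite(G)), all(is.finite(F_cyto)),
            length(F_cyto) == length(G), is.finite(G_S))
  structure(list(G = G, F_cyto = as.numeric(F_cyto), G_S = G_S),
            class = "toy_ensemble_spec")
}

#' Exact equilibrium distribution of a toy space
#'
#' `P(j) = exp(-zeta G_j) / Z` with `Z = sum_j exp(-zeta G_j)`, by direct
#' summation.
#'
#' @param spec A [toy_ensemble_spec()].
#' @param zeta Distribution parameter.
#' @return Probability vector over states.
#' @export
toy_peq <- function(spec, zeta) {
  lw <- -zeta * spec$G
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' @rdname toy_peq
#' @export
toy_mean_G <- function(spec, zeta) sum(toy_peq(spec, zeta) * spec$G)

#' @export
solve_zeta.toy_ensemble_spec <- function(env, params = NULL, seed = NULL,
                                         tol_G = 1e-10, ...) {
  spec <- env
  GS <- spec$G_S
  if (stats::var(spec$G) == 0 || diff(range(spec$G)) == 0) {
    return(1)  # documented tie-break: constraint holds for every zeta
  }
  if (GS < min(spec$G) || GS > max(spec$G)) {
    stop("target mean outside the reachable range of G: no zeta satisfies the constraint",
         call. = FALSE)
  }
  f <- function(z) toy_mean_G(spec, z) - GS
  lo <- -1; hi <- 1
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 2       # mean decreases in zeta
  while (f(lo) < 0 && lo > -1e8) lo <- lo * 2
  stats::uniroot(f, c(lo, hi), tol = tol_G)$root
}

#' Discrete Metropolis chain on a toy space
#'
#' Symmetric uniform proposals over the states, acceptance
#' `min(1, exp(-zeta dG))`; the long-run empirical distribution converges
#' to [toy_peq()].
#'
#' @param spec A [toy_ensemble_spec()].
#' @param zeta Distribution parameter.
#' @param n_steps Chain length.
#' @param seed RNG seed.
#' @return Integer vector of visited state indices.
#' @export
toy_metropolis <- function(spec, zeta, n_steps, seed) {
  set.seed(seed %% .Machine$integer.max)
  n <- length(spec$G)
  out <- integer(n_steps)
  cur <- 1L
  props <- sample.int(n, n_steps, replace = TRUE)
  us <- stats::runif(n_steps)
  for (s in seq_len(n_steps)) {
    j <- props[s]
    dG <- spec$G[j] - spec$G[cur]
    if (dG <= 0 || us[s] < exp(-zeta * dG)) cur <- j
    out[s] <- cur
  }
  out
}

#' Wrap a toy space as a forecast-ready ensemble
#'
#' Builds a `homeostatic_ensemble`-compatible tibble whose rows are
#' drawn (exactly, by direct multinomial sampling from [toy_peq()], or
#' deterministically by expected counts) from the toy equilibrium
#' distribution, so that [ensemble_statistics()] and [forecast()] run on
#' enumerable fixtures.
#'
#' @param spec A [toy_ensemble_spec()].
#' @param zeta Distribution parameter; solved from the homeostatic
#'   constraint when `NULL`.
#' @param n Number of rows.
#' @param seed RNG seed (ignored for `method = "expected"`).
#' @param method `"sample"` (multinomial draws) or `"expected"`
#'   (deterministic rounded expected counts).
#' @return A tibble with columns `state`, `G`, `F_cyto` and attribute
#'   `zeta`.
#' @export
make_toy_ensemble <- function(spec, zeta = NULL, n = 1000L, seed = 1L,
                              method = c("sample", "expected")) {
  stopifnot(inherits(spec, "toy_ensemble_spec"))
  method <- match.arg(method)
  if (is.null(zeta)) zeta <- solve_zeta(spec)
  p <- toy_peq(spec, zeta)
  idx <- if (method == "sample") {
    set.seed(seed %% .Machine$integer.max)
    sample.int(length(p), n, replace = TRUE, prob = p)
  } else {
    rep(seq_along(p), times = round(p * n))
  }
  tb <- tibble::tibble(state = idx, G = spec$G[idx],
                       F_cyto = spec$F_cyto[idx])
  attr(tb, "zeta") <- zeta
  attr(tb, "G_S") <- spec$G_S
  tb
}
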