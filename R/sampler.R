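# Homeostatic-ensemble construction: Metropolis MCMC over morphological
# microstates targeting P(j) ~ exp(-zeta G(j)), with zeta solved so that
# <G> = G_S (the suspension energy).

new_ensemble <- function(samples, coefficients, zeta, params, env, seed,
                         diagnostics) {
  tb <- tibble::as_tibble(samples)
  attr(tb, "coefficients") <- coefficients
  attr(tb, "zeta") <- zeta
  attr(tb, "params") <- params
  attr(tb, "env") <- env
  attr(tb, "seed") <- seed
  attr(tb, "diagnostics") <- diagnostics
  attr(tb, "fingerprint") <- config_fingerprint(params, env)
  class(tb) <- c("homeostatic_ensemble", class(tb))
  tb
}

#' @export
print.homeostatic_ensemble <- function(x, ...) {
  d <- attr(x, "diagnostics")
  env <- attr(x, "env")
  cat(sprintf("<homeostatic_ensemble> %d samples, zeta = %.4g, %s\n",
              nrow(x), attr(x, "zeta"),
              if (env$kind == "elastic_uniform")
                sprintf("E_sub = %g kPa", env$E_sub)
              else sprintf("island A_p = %g um^2", env$A_p)))
  cat(sprintf("  acceptance %.1f%%, <G> = %.4f (G_S = %.4f), Rhat(G) = %.3f\n",
              100 * d$acceptance_rate, mean(x$G), attr(x, "params")$G_S,
              d$rhat_G))
  NextMethod()
}

# turn kernel stats matrix into the observable tibble
stats_to_tibble <- function(stats, stat_names, params, step) {
  colnames(stats) <- stat_names
  tb <- tibble::as_tibble(stats)
  ar <- function(Ixx, Ixy, Iyy) {
    lam1 <- (Ixx + Iyy) / 2 + sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
    lam2 <- (Ixx + Iyy) / 2 - sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
    sqrt(lam1 / pmax(lam2, 1e-300))
  }
  tibble::tibble(
    step = step,
    G = tb$G, F_passive = tb$F_passive, F_cyto = tb$F_cyto,
    F_sub = tb$F_sub, T_total = tb$T_total,
    N_u = tb$N_u, N_b = 1 - tb$N_u,
    area = tb$area, A_hat = tb$area / (pi * params$R0^2),
    aspect_ratio = ar(tb$Ixx, tb$Ixy, tb$Iyy))
}

# feasible initial coefficients for an environment (shrunk circle when the
# island is smaller than the resting cell)
initial_coefficients <- function(env, params) {
  cvec <- rep(0, SHAPE_K)
  if (env$kind == "rigid_island") {
    hs <- sqrt(env$A_p) / 2
    if (hs < params$R0 * 1.02) {
      lam <- 0.95 * hs / params$R0
      cvec[c(1, 4)] <- lam - 1
    }
  }
  cvec
}

#' Metropolis chain over morphological microstates
#'
#' Samples the Boltzmann-like distribution `P(j) ~ exp(-zeta G(j))` over
#' cell shapes with symmetric Gaussian proposals on the 20 shape
#' coefficients. Step scales are adapted during burn-in toward 25-35%
#' acceptance and then frozen, so production sampling satisfies detailed
#' balance. Degenerate proposals (non-positive Jacobian,
#' self-intersecting footprint, island violation) are rejected. Fully
#' reproducible: the same `seed` and configuration give bitwise identical
#' chains.
#'
#' @param env A [env_elastic()] or [env_island()] environment.
#' @param params A [cell_parameters()] object.
#' @param zeta Homeostatic distribution parameter (> 0), in 1/energy
#'   units of `1/E_norm`.
#' @param n_steps Number of production Metropolis steps.
#' @param seed Integer RNG seed.
#' @param thin Keep every `thin`-th production step.
#' @param burn_frac Burn-in length as a fraction of `n_steps` (adaptive,
#'   discarded).
#' @param step_sd Initial proposal standard deviation (scalar or length
#'   20); adapted during burn-in.
#' @param init Optional initial [shape_state()] or coefficient vector.
#' @param ctx Optional precomputed [model_context()].
#' @return A `homeostatic_ensemble` tibble (one row per retained sample:
#'   energies, observables) with the coefficient matrix, chain
#'   diagnostics, `zeta` and configuration attached as attributes.
#' @examples
#' \donttest{
#' p <- cell_parameters()
#' p <- suspension_energy(p)$params
#' e <- metropolis_chain(env_elastic(30), p, zeta = 2, n_steps = 2000,
#'                       seed = 1)
#' }
#' @export
metropolis_chain <- function(env, params, zeta, n_steps, seed, thin = 10L,
                             burn_frac = 0.2, step_sd = 0.02, init = NULL,
                             ctx = NULL) {
  stopifnot(zeta > 0, n_steps >= 1)
  if (is.null(ctx)) ctx <- model_context(params, env)
  pv <- params_vector(params)
  sd_vec <- rep(step_sd, length.out = SHAPE_K)
  cvec <- if (is.null(init)) initial_coefficients(env, params)
          else if (inherits(init, "shape_state")) init$coefficients
          else as.numeric(init)

  set.seed(seed %% .Machine$integer.max)

  # adaptive burn-in in segments; adaptation frozen before production
  n_burn <- ceiling(burn_frac * n_steps)
  n_seg <- 10L
  seg <- max(50L, ceiling(n_burn / n_seg))
  acc_hist <- numeric(0)
  for (i in seq_len(n_seg)) {
    res <- .run_chain_cpp(cvec, unclass(ctx), pv, zeta, seg, sd_vec,
                          thin = seg)
    acc <- res$n_accept / res$n_steps
    acc_hist <- c(acc_hist, acc)
    sd_vec <- sd_vec * exp(1.2 * (acc - 0.30))
    sd_vec <- pmin(pmax(sd_vec, 1e-4), 0.5)
    cvec <- drop(res$final)
  }

  res <- .run_chain_cpp(cvec, unclass(ctx), pv, zeta, as.integer(n_steps),
                        sd_vec, thin = as.integer(thin))
  acc_rate <- res$n_accept / res$n_steps
  if (acc_rate < 0.01 && step_sd[1] > 2e-4) {
    # frozen chain (e.g. tightly confined island): retry once with much
    # smaller proposals before giving up
    return(metropolis_chain(env, params, zeta, n_steps, seed,
                            thin = thin, burn_frac = burn_frac,
                            step_sd = step_sd / 10, init = init, ctx = ctx))
  }
  if (acc_rate < 0.01) {
    stop(sprintf(paste0(
      "chain acceptance rate %.2f%% after adaptation; ",
      "reduce step_sd or revisit zeta"), 100 * acc_rate), call. = FALSE)
  }
  samples <- stats_to_tibble(res$stats, as.character(res$stat_names), params,
                             step = seq_len(nrow(res$stats)) * thin)
  diagnostics <- list(
    acceptance_rate = acc_rate, burn_acceptance = acc_hist,
    step_sd = sd_vec, n_steps = n_steps, n_burn = n_burn, thin = thin,
    tau_G = autocorrelation_time(samples$G),
    rhat_G = split_rhat(samples$G))
  new_ensemble(samples, res$coefficients, zeta, params, env, seed,
               diagnostics)
}

# integrated autocorrelation time (initial positive sequence estimator)
autocorrelation_time <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  max(1, 1 + 2 * sum(rho))
}

# split-chain potential scale reduction on a single chain
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 5) return(NA_real_)
  a <- x[seq_len(n)]; b <- x[seq_len(n) + n]
  W <- (stats::var(a) + stats::var(b)) / 2
  B <- n * stats::var(c(mean(a), mean(b)))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Solve the homeostatic constraint for zeta
#'
#' Finds the distribution parameter `zeta*` such that the ensemble
#' average Gibbs energy equals the suspension energy,
#' `<G>_zeta* = G_S`, by stochastic root-finding: pilot chains estimate
#' `<G>` at the current `zeta`, importance reweighting of the pilot
#' samples gives a local model of `<G>(zeta)` (whose derivative is
#' `-Var(G) <= 0`, so the mean is monotone decreasing in `zeta`), and the
#' root of the reweighted mean is taken as the next iterate. A final
#' production chain is run at `zeta*` and the constraint re-verified on
#' it.
#'
#' @param env,params Environment and cell parameters (`G_S` is computed
#'   from [suspension_energy()] if not cached).
#' @param seed Integer seed; every chain in the solve consumes a seed
#'   derived from it.
#' @param tol_G Convergence tolerance on `|<G> - G_S|`; default 1% of
#'   `max(1, |G_S|)`.
#' @param n_steps Production chain length (post burn-in Metropolis steps).
#' @param pilot_steps Pilot chain length per solver iteration.
#' @param zeta0 Starting value.
#' @param max_iter Maximum solver iterations.
#' @param thin Thinning of the production chain.
#' @param verbose Print solver progress.
#' @return The production `homeostatic_ensemble` at `zeta*` (attribute
#'   `zeta`; diagnostics record the solve path).
#' @examples
#' \donttest{
#' e <- solve_zeta(env_elastic(30), cell_parameters(), seed = 1,
#'                 n_steps = 5000, pilot_steps = 2000)
#' attr(e, "zeta")
#' }
#' @export
solve_zeta <- function(env, params, seed, tol_G = NULL, n_steps = 2e4,
                       pilot_steps = 5000, zeta0 = 1, max_iter = 12L,
                       thin = 10L, verbose = FALSE) {
  UseMethod("solve_zeta")
}

# pooled multiple-importance-sampling estimate of <G>(zeta) from pilot
# chains run at several zeta values (balance heuristic over the mixture);
# returns a function of zeta with the mixture part precomputed
make_pooled_mean_G <- function(G_all, zeta_src, n_src) {
  # log mixture density (up to the common shape-space factor) per sample
  lw_mat <- outer(G_all, zeta_src, function(g, z) -z * g) +
    matrix(log(n_src), length(G_all), length(n_src), byrow = TRUE)
  mx <- apply(lw_mat, 1, max)
  lmix <- mx + log(rowSums(exp(lw_mat - mx)))
  function(zeta) {
    lw <- -zeta * G_all - lmix
    lw <- lw - max(lw)
    w <- exp(lw)
    sum(w * G_all) / sum(w)
  }
}

#' @export
solve_zeta.cell_env <- function(env, params, seed, tol_G = NULL,
                                n_steps = 2e4, pilot_steps = 5000,
                                zeta0 = 1, max_iter = 12L, thin = 10L,
                                verbose = FALSE) {
  params <- ensure_GS(params)
  GS <- params$G_S
  if (is.null(tol_G)) tol_G <- 0.01 * max(1, abs(GS))
  ctx <- model_context(params, env)
  zeta <- zeta0
  zeta_floor <- 1e-3
  unreachable <- FALSE
  path <- list()
  init <- NULL
  step_sd <- 0.02
  pool_G <- list(); pool_zeta <- numeric(0); pool_n <- numeric(0)
  for (it in seq_len(max_iter)) {
    sd_i <- (seed + 7919 * it) %% .Machine$integer.max
    pil <- metropolis_chain(env, params, zeta, pilot_steps, seed = sd_i,
                            thin = max(2L, thin %/% 2L), step_sd = step_sd,
                            init = init, ctx = ctx)
    init <- drop(utils::tail(attr(pil, "coefficients"), 1))
    step_sd <- attr(pil, "diagnostics")$step_sd
    G <- pil$G
    m <- mean(G); v <- stats::var(G)
    pool_G[[it]] <- G; pool_zeta <- c(pool_zeta, zeta)
    pool_n <- c(pool_n, length(G))
    path[[it]] <- c(zeta = zeta, mean_G = m, var_G = v)
    if (verbose) message(sprintf("  it %d: zeta = %.4g, <G> = %.4f (G_S = %.4f)",
                                 it, zeta, m, GS))
    if (v <= 0 && abs(m - GS) <= tol_G) { zeta <- 1; break }  # degenerate
    # root of the pooled estimate of <G>(zeta), which is monotone
    # decreasing (derivative -Var(G))
    # sliding window: early pilots may predate chain equilibration
    keep <- max(1, it - 5):it
    G_all <- unlist(pool_G[keep])
    pm <- make_pooled_mean_G(G_all, pool_zeta[keep], pool_n[keep])
    f <- function(z) pm(z) - GS
    # trust region: the pooled estimate is only reliable near visited
    # zeta values, so move at most a factor 3 per iteration
    lo <- zeta / 3; hi <- zeta * 3
    if (f(hi) > 0) {
      if (zeta > 1e6) {
        stop("G_S appears below the minimum reachable G: no zeta satisfies the homeostatic constraint",
             call. = FALSE)
      }
      znew <- hi
    } else if (f(lo) < 0) {
      if (zeta <= zeta_floor) {
        # confinement can truncate the high-energy states needed to
        # reach the homeostatic setpoint; report the maximum-entropy
        # (zeta -> 0) ensemble, flagged as unreachable
        unreachable <- TRUE
        zeta <- zeta_floor
        break
      }
      znew <- max(lo, zeta_floor)
    } else {
      znew <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    }
    # stop once the update stabilizes and the pilot mean is consistent
    tau <- autocorrelation_time(G)
    se_m <- stats::sd(G) * sqrt(tau / length(G))
    if (it >= 3 && abs(znew - zeta) <= 0.02 * zeta &&
        abs(m - GS) <= max(tol_G, 2 * se_m)) { zeta <- znew; break }
    zeta <- znew
  }
  prod <- metropolis_chain(env, params, zeta, n_steps,
                           seed = (seed + 104729) %% .Machine$integer.max,
                           thin = thin, step_sd = step_sd, init = init,
                           ctx = ctx)
  d <- attr(prod, "diagnostics")
  d$solve_path <- do.call(rbind, path)
  d$constraint_gap <- mean(prod$G) - GS
  d$tol_G <- tol_G
  d$setpoint_unreachable <- unreachable
  d$converged <- !unreachable &&
    abs(d$constraint_gap) <= max(tol_G, 3 * stats::sd(prod$G) *
                                   sqrt(d$tau_G / nrow(prod)))
  attr(prod, "diagnostics") <- d
  if (unreachable) {
    warning("homeostatic setpoint unreachable under this confinement; returning the maximum-entropy (zeta -> 0) ensemble",
            call. = FALSE)
  } else if (!d$converged) {
    warning(sprintf("homeostatic constraint gap %.4f exceeds tolerance %.4f on the production chain",
                    d$constraint_gap, tol_G), call. = FALSE)
  }
  prod
}

#' Ensemble summary statistics of an observable
#'
#' Sample mean, standard deviation, a Gaussian-kernel density estimate
#' (Silverman bandwidth) and Monte-Carlo standard errors (via the
#' integrated autocorrelation time) of one ensemble column.
#'
#' @param ensemble A `homeostatic_ensemble` (or any data frame of
#'   samples).
#' @param observable Column name, e.g. `"F_cyto"`.
#' @param n_grid Density grid size.
#' @return A list: `mean`, `sd`, `var`, `se_mean`, `tau` (autocorrelation
#'   time), `n_eff`, and `density` (tibble with `x`, `y`).
#' @export
ensemble_statistics <- function(ensemble, observable = "F_cyto",
                                n_grid = 512) {
  if (!observable %in% names(ensemble)) {
    stop(sprintf("observable '%s' not found in ensemble", observable),
         call. = FALSE)
  }
  x <- ensemble[[observable]]
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  tau <- autocorrelation_time(x)
  bw <- if (s > 0) stats::bw.nrd0(x) else 1e-6 * max(1, abs(x[1]))
  d <- stats::density(x, bw = bw, n = n_grid)
  list(mean = mean(x), sd = s, var = s^2,
       se_mean = s * sqrt(tau / length(x)), tau = tau,
       n_eff = length(x) / tau,
       density = tibble::tibble(x = d$x, y = d$y))
}
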