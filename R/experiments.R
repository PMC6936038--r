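# End-to-end in-silico experiments: stiffness sweeps, adhesive-island
# sweeps, and the ROCK-inhibition comparison.

condition_seed <- function(seed, i) (seed + 15485863 * i) %% .Machine$integer.max

run_condition <- function(env, params, seed, n_steps, pilot_steps, thin,
                          verbose = FALSE) {
  label <- if (env$kind == "elastic_uniform") {
    sprintf("E_sub = %g kPa", env$E_sub)
  } else {
    sprintf("A_p = %g um^2", env$A_p)
  }
  if (verbose) message("sampling ", label)
  # a non-converged ensemble is flagged in its diagnostics, not fatal
  withCallingHandlers(
    solve_zeta(env, params, seed = seed, n_steps = n_steps,
               pilot_steps = pilot_steps, thin = thin, verbose = verbose),
    warning = function(w) {
      if (verbose) message("  note: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
}

condition_summary <- function(ens, condition) {
  st <- ensemble_statistics(ens, "F_cyto")
  d <- attr(ens, "diagnostics")
  tibble::tibble(
    condition = condition,
    zeta = attr(ens, "zeta"),
    mu = st$mean, sigma = st$sd, se_mu = st$se_mean,
    mean_A_hat = mean(ens$A_hat),
    mean_aspect_ratio = mean(ens$aspect_ratio),
    mean_T_total = mean(ens$T_total),
    mean_N_b = mean(ens$N_b),
    iqr_A_hat = stats::IQR(ens$A_hat),
    iqr_aspect_ratio = stats::IQR(ens$aspect_ratio),
    iqr_T_total = stats::IQR(ens$T_total),
    mean_G = mean(ens$G), G_S = attr(ens, "params")$G_S,
    acceptance = d$acceptance_rate, rhat_G = d$rhat_G,
    converged = isTRUE(d$converged))
}

forecast_table <- function(ensembles, conditions, media) {
  purrr::map2_dfr(ensembles, conditions, function(e, cond) {
    fc <- forecast(e, media)
    dplyr::mutate(tibble::as_tibble(fc), condition = cond,
                  .before = 1)
  })
}

write_sweep_csvs <- function(res, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$conditions,
                   file.path(out_dir, "conditions.csv"), row.names = FALSE)
  utils::write.csv(res$forecasts,
                   file.path(out_dir, "forecasts.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Stiffness sweep: sample, summarize and forecast per substrate
#'
#' For each substrate stiffness: solve the homeostatic constraint,
#' sample the production ensemble, and summarize the observables and the
#' `F_cyto` distribution. Lineage bands are then either recalibrated on
#' this sweep against observed differentiation fractions (the default,
#' mirroring the calibrate-then-predict workflow) or taken as given, and
#' every condition is forecast.
#'
#' @param stiffness Substrate stiffness values, kPa.
#' @param params A [cell_parameters()] object.
#' @param seed Integer seed (each condition derives its own).
#' @param n_steps Production Metropolis steps per condition.
#' @param pilot_steps Pilot chain length for the zeta solve.
#' @param thin Production thinning.
#' @param media A [media_model()] used as-is when `recalibrate = FALSE`.
#' @param recalibrate Calibrate bands on this sweep (default).
#' @param observed Observed fractions for calibration (default
#'   [reference_fractions()] for growth media, matched by condition).
#' @param out_dir Optional directory for CSV outputs.
#' @param verbose Progress messages.
#' @return A list of class `sweep_result`: `conditions` (per-condition
#'   summary tibble), `forecasts` (per-condition, per-lineage tibble),
#'   `media` (the bands used), `ensembles` (named list).
#' @export
run_stiffness_sweep <- function(stiffness = c(1, 3, 10, 30, 70),
                                params = cell_parameters(), seed = 1L,
                                n_steps = 2e4, pilot_steps = 4000,
                                thin = 10L, media = growth_media(),
                                recalibrate = TRUE,
                                observed = reference_fractions("growth"),
                                out_dir = NULL, verbose = FALSE) {
  stopifnot(length(stiffness) >= 1)
  params <- ensure_GS(params)
  ensembles <- purrr::imap(stats::setNames(stiffness, stiffness),
                           function(E, nm) {
    i <- match(E, stiffness)
    run_condition(env_elastic(as.numeric(E)), params,
                  seed = condition_seed(seed, i), n_steps = n_steps,
                  pilot_steps = pilot_steps, thin = thin, verbose = verbose)
  })
  conditions <- purrr::map2_dfr(ensembles, stiffness, condition_summary)
  if (recalibrate) {
    obs <- observed[observed$condition %in% stiffness, ]
    media <- calibrate_bands(conditions, obs, Nc = attr(media, "Nc"),
                             media = paste0(attr(media, "media"),
                                            "_recalibrated"))
  }
  res <- structure(list(conditions = conditions,
                        forecasts = forecast_table(ensembles, stiffness,
                                                   media),
                        media = media, ensembles = ensembles,
                        sweep = "stiffness"),
                   class = "sweep_result")
  write_sweep_csvs(res, out_dir)
  res
}

#' Island-area sweep on rigid substrates
#'
#' As [run_stiffness_sweep()], over square adhesive islands of the given
#' areas, plus (optionally) the unpatterned stiff-substrate reference
#' ensemble at `E_ref` for convergence comparison: for large enough
#' islands confinement no longer binds and the island ensembles approach
#' the unpatterned reference.
#'
#' @param areas Island areas, um^2.
#' @param E_ref Reference unpatterned stiffness, kPa (`NULL` to skip).
#' @param media A [media_model()]; typically the bands calibrated on a
#'   stiffness sweep (predict-on-a-new-cue workflow), so no
#'   recalibration happens here by default.
#' @inheritParams run_stiffness_sweep
#' @return A `sweep_result`; the reference ensemble (if any) appears as
#'   condition `Inf` in `conditions` and `"reference"` in `ensembles`.
#' @export
run_island_sweep <- function(areas = c(900, 1600, 2025, 2725, 4900, 8100,
                                       11025, 14400),
                             params = cell_parameters(), seed = 1L,
                             n_steps = 2e4, pilot_steps = 4000, thin = 10L,
                             media = growth_media(), E_ref = 70,
                             out_dir = NULL, verbose = FALSE) {
  stopifnot(length(areas) >= 1)
  params <- ensure_GS(params)
  ensembles <- purrr::imap(stats::setNames(areas, areas), function(A, nm) {
    i <- match(A, areas)
    run_condition(env_island(as.numeric(A)), params,
                  seed = condition_seed(seed, 100 + i), n_steps = n_steps,
                  pilot_steps = pilot_steps, thin = thin, verbose = verbose)
  })
  conds <- as.numeric(areas)
  if (!is.null(E_ref)) {
    ensembles$reference <- run_condition(env_elastic(E_ref), params,
                                         seed = condition_seed(seed, 99),
                                         n_steps = n_steps,
                                         pilot_steps = pilot_steps,
                                         thin = thin, verbose = verbose)
    conds <- c(conds, Inf)
  }
  conditions <- purrr::map2_dfr(ensembles, conds, condition_summary)
  res <- structure(list(conditions = conditions,
                        forecasts = forecast_table(ensembles, conds, media),
                        media = media, ensembles = ensembles,
                        sweep = "island"),
                   class = "sweep_result")
  write_sweep_csvs(res, out_dir)
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s sweep, %d conditions\n", x$sweep,
              nrow(x$conditions)))
  print(x$conditions[, c("condition", "zeta", "mu", "sigma", "mean_A_hat",
                         "mean_N_b", "converged")])
  invisible(x)
}

#' ROCK-inhibition comparison
#'
#' Paired untreated/treated ensembles on one adhesive island, where
#' treatment with a ROCK inhibitor is modelled as a reduction of the
#' maximum fibre tension `sigma_max` (default 240 -> 231 kPa; the
#' suspension reference `G_S` is recomputed for the treated cell).
#' Both arms are driven by common random numbers (the same seed), the
#' standard paired-simulation design, so the comparison isolates the
#' contractility effect from Monte-Carlo noise. Reports both forecasts
#' and the comparative L1 statistics: the distributions of the direct
#' observables (`A_hat`, `aspect_ratio`, `T_total`) barely move, while
#' the `F_cyto` distribution shifts upward.
#'
#' @param A_p Island area, um^2.
#' @param sigma_untreated,sigma_treated Fibre tension ceilings, kPa.
#' @param media A [media_model()] (typically mixed-media bands
#'   calibrated on an island sweep).
#' @inheritParams run_stiffness_sweep
#' @return A list of class `rock_result`: `ensembles` (untreated,
#'   treated), `forecasts`, `l1` (per-observable L1 distances),
#'   `delta_mu` (treated minus untreated mean `F_cyto`).
#' @export
run_rock_inhibition <- function(A_p = 2725, sigma_untreated = 240,
                                sigma_treated = 231,
                                params = cell_parameters(), seed = 1L,
                                n_steps = 2e4, pilot_steps = 4000,
                                thin = 10L, media = mixed_media(),
                                out_dir = NULL, verbose = FALSE) {
  env <- env_island(A_p)
  p_un <- params; p_un$sigma_max <- sigma_untreated; p_un$G_S <- NULL
  p_tr <- params; p_tr$sigma_max <- sigma_treated; p_tr$G_S <- NULL
  p_un <- ensure_GS(p_un); p_tr <- ensure_GS(p_tr)
  # common random numbers: both arms run from the same seed so the
  # paired comparison isolates the sigma_max effect from chain noise
  ens <- list(
    untreated = run_condition(env, p_un, seed = condition_seed(seed, 201),
                              n_steps = n_steps, pilot_steps = pilot_steps,
                              thin = thin, verbose = verbose),
    treated = run_condition(env, p_tr, seed = condition_seed(seed, 201),
                            n_steps = n_steps, pilot_steps = pilot_steps,
                            thin = thin, verbose = verbose))
  l1 <- tibble::tibble(
    observable = c("A_hat", "aspect_ratio", "T_total", "F_cyto"),
    l1 = vapply(c("A_hat", "aspect_ratio", "T_total", "F_cyto"),
                function(v) density_l1(ens$untreated[[v]],
                                       ens$treated[[v]]), 0))
  res <- structure(list(
    ensembles = ens,
    forecasts = forecast_table(ens, c("untreated", "treated"), media),
    l1 = l1,
    delta_mu = mean(ens$treated$F_cyto) - mean(ens$untreated$F_cyto),
    delta_N_b = mean(ens$treated$N_b) - mean(ens$untreated$N_b)),
    class = "rock_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$forecasts, file.path(out_dir, "rock_forecasts.csv"),
                     row.names = FALSE)
    utils::write.csv(res$l1, file.path(out_dir, "rock_l1.csv"),
                     row.names = FALSE)
  }
  res
}

#' @export
print.rock_result <- function(x, ...) {
  cat("<rock_result>\n")
  cat(sprintf("  delta mean F_cyto (treated - untreated) = %.4f\n",
              x$delta_mu))
  cat(sprintf("  delta mean N_b = %.4f\n", x$delta_N_b))
  print(x$l1)
  invisible(x)
}
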