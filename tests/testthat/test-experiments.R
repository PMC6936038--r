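# Toy-ensemble plumbing and end-to-end sweep mechanics (desk-scale).

test_that("make_toy_ensemble exposes the exact equilibrium distribution", {
  toy <- toy_ensemble_spec(c(0, 1, 2), F_cyto = c(2.6, 1.9, 1.6))
  z <- 0.7
  p_exact <- exp(-z * toy$G) / sum(exp(-z * toy$G))
  expect_equal(toy_peq(toy, z), p_exact, tolerance = 1e-14)

  ens <- make_toy_ensemble(toy, zeta = z, n = 3000, method = "expected")
  emp <- tabulate(ens$state, 3) / nrow(ens)
  expect_equal(emp, p_exact, tolerance = 1e-3)

  # all-equal energies: uniform equilibrium
  flat <- toy_ensemble_spec(c(1, 1, 1, 1))
  expect_equal(toy_peq(flat, 2.3), rep(0.25, 4))

  # same zeta* as the enumeration example when built via the constraint
  toy2 <- toy_ensemble_spec(c(0, 1, 2), G_S = 0.8)
  e2 <- make_toy_ensemble(toy2, n = 100)
  expect_equal(attr(e2, "zeta"), solve_zeta(toy2), tolerance = 1e-12)

  expect_error(toy_ensemble_spec(numeric(0)), "non-empty")
})

test_that("a single-condition sweep runs end to end and writes auditable CSVs", {
  p <- test_params_gs()
  out <- withr::local_tempdir()
  sw <- suppressWarnings(run_stiffness_sweep(
    stiffness = 30, params = p, seed = 5, n_steps = 2500,
    pilot_steps = 800, recalibrate = FALSE, media = growth_media(),
    out_dir = out))
  expect_s3_class(sw$conditions, "tbl_df")
  expect_identical(nrow(sw$conditions), 1L)
  expect_setequal(unique(sw$forecasts$lineage),
                  c("osteoblast", "myoblast", "undifferentiated"))
  expect_true(file.exists(file.path(out, "conditions.csv")))
  got <- utils::read.csv(file.path(out, "conditions.csv"))
  expect_equal(got$zeta, sw$conditions$zeta, tolerance = 1e-12)

  # end-to-end determinism: identical config + seed reproduces the table
  sw2 <- suppressWarnings(run_stiffness_sweep(
    stiffness = 30, params = p, seed = 5, n_steps = 2500,
    pilot_steps = 800, recalibrate = FALSE, media = growth_media()))
  expect_identical(sw$conditions$mu, sw2$conditions$mu)
  expect_identical(sw$conditions$zeta, sw2$conditions$zeta)
})

test_that("tidiers and plots expose ensemble and forecast summaries", {
  p <- test_params_gs()
  e <- cached("ens_30_quick",
              suppressWarnings(solve_zeta(env_elastic(30), p, seed = 21,
                                          n_steps = 8000,
                                          pilot_steps = 2500)))
  g <- glance(e)
  expect_identical(nrow(g), 1L)
  expect_equal(g$mean_G, mean(e$G))
  td <- tidy(e)
  expect_false(inherits(td, "homeostatic_ensemble"))
  expect_identical(nrow(td), nrow(e))

  fc <- forecast(e, growth_media())
  expect_s3_class(autoplot(fc), "ggplot")
  expect_s3_class(autoplot(e), "ggplot")
  expect_equal(glance(fc)$undifferentiated,
               fc$p[fc$lineage == "undifferentiated"])
})

test_that("island-size cues mirror stiffness cues through F_cyto", {
  # reuses ensembles cached by the acceptance suite where possible
  e900 <- cached("acc_island_900", suppressWarnings(
    solve_zeta(env_island(900), ensure_GS(cell_parameters()),
               seed = 7301 + 900, n_steps = 2e4, pilot_steps = 3000)))
  e2725 <- cached("acc_rock", {
    sw <- cached("acc_sweep", suppressWarnings(
      run_stiffness_sweep(stiffness = c(1, 3, 10, 30, 70),
                          params = cell_parameters(), seed = 7301,
                          n_steps = 3e4, pilot_steps = 3500)))
    mm <- calibrate_bands(sw$conditions, reference_fractions("mixed"),
                          Nc = 15)
    suppressWarnings(run_rock_inhibition(A_p = 2725,
                                         params = cell_parameters(),
                                         seed = 7301, n_steps = 8e4,
                                         pilot_steps = 3500, media = mm))
  })$ensembles$untreated
  e11025 <- cached("acc_island_11025", suppressWarnings(
    solve_zeta(env_island(11025), ensure_GS(cell_parameters()),
               seed = 7301 + 25, n_steps = 3e4, pilot_steps = 3500)))

  # relaxing confinement cannot shrink the reachable set: mean area grows
  areas <- c(mean(e900$A_hat), mean(e2725$A_hat), mean(e11025$A_hat))
  expect_true(all(diff(areas) > 0))
  # cue equivalence: larger islands lower F_cyto, like stiffer substrates
  mus <- c(mean(e900$F_cyto), mean(e2725$F_cyto), mean(e11025$F_cyto))
  expect_true(all(diff(mus) < 0))

  # growth media: osteoblast commitment favoured at intermediate-large
  # islands over strongly confining ones
  media <- cached("acc_sweep", NULL)$media
  osteo <- function(e) {
    fc <- forecast(e, media)
    fc$p_raw[fc$lineage == "osteoblast"]
  }
  expect_gt(osteo(e2725), osteo(e900))
})
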