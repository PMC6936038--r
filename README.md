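# homeostat

Simulation of the homeostatic ensemble of single-cell shapes and
free-energy-based forecasting of human mesenchymal stem cell (hMSC)
lineage commitment.

## The problem

When hMSCs are seeded on substrates of different stiffness, on
micro-patterned adhesive islands of different size, or treated with
contractility inhibitors, they commit to different lineages —
osteoblasts on stiff substrates and large islands, myoblasts at
intermediate stiffness, adipocytes on soft substrates and small
islands. Morphological observables (cell area, aspect ratio, traction)
respond to these cues too, but their distributions overlap so strongly
across conditions that no single observable predicts fate. `homeostat`
implements a statistical-mechanics model in which the *cytoskeletal
free energy* — a scalar summary of the biochemical state of the
stress-fibre cytoskeleton — is the forecasting metric, and reproduces
in silico the classic stiffness, island-size and ROCK-inhibition
experiments.

It is aimed at mechanobiology modellers who want a fast, reproducible,
fully scriptable implementation of the homeostatic-mechanics
framework: sample morphological microstates, compute energies,
tractions and morphometrics, and turn ensemble statistics into lineage
probabilities.

## The model in brief

A morphological microstate `j` is a smooth 2D deformation of the
resting circular cell (20 shape coefficients) together with its
equilibrated stress-fibre cytoskeleton. Its normalized Gibbs free
energy is

    G(j) = F_passive(j) + F_cyto(j) + F_sub(j)

(compressible 2D Ogden elasticity of cytoplasm and nucleus; Langmuir
binding equilibrium of stress-fibre proteins against a uniform unbound
pool, with a stiffness-dependent stall-tension ceiling; Winkler
substrate energy of the traction field). The cell fluctuates over the
**homeostatic ensemble**

    P_eq(j) = exp(-zeta G(j)) / Z,     <G> = G_S,

where `G_S` is the suspension free energy and the homeostatic
temperature `1/zeta` is solved from the constraint. Sampling is
Metropolis MCMC (compiled kernel, ~0.4 ms per energy evaluation).

Fate is forecast from the ensemble mean and standard deviation
`(mu, sigma)` of `F_cyto`: over the 24-48 h commitment window the cell
visits `Nc` decorrelated microstates, so its time-averaged cytoskeletal
free energy is `N(mu, sigma^2/Nc)`; lineage `x` is chosen when that
average lands in the band `centre_x ± half_width_x`, with
`Z_L = max(1, sum Px)` normalizing lineages plus non-differentiation
to one. Bands are media-specific and calibrated on one cue family
(stiffness), then used to predict another (island size, ROCK
inhibition).

See the vignette (`vignettes/homeostatic-forecasting.Rmd`) for the
full closure, parameter table and numerical choices.

## Worked example

```r
library(homeostat)

params <- cell_parameters()          # documented defaults
susp   <- suspension_energy(params)  # reference state of the constraint
susp$lambda_s                        # 0.930  (suspended cell is contracted)
susp$G_S                             # -8.667 (normalized suspension energy)

# homeostatic ensemble on a 30 kPa substrate
ens <- solve_zeta(env_elastic(30), susp$params, seed = 42,
                  n_steps = 20000, pilot_steps = 4000)
glance(ens)
#>    zeta n_samples n_steps acceptance_rate mean_G   G_S constraint_gap tau_G
#> 1 0.965      2000   20000           0.273  -9.05 -8.67         -0.379  44.6

mean(ens$A_hat)   # 2.347  -- cells spread to ~2.3x their resting area
mean(ens$N_b)     # 0.793  -- high stress-fibre polymerization
ensemble_statistics(ens, "F_cyto")[c("mean", "sd")]
#> $mean [1] -14.664      $sd [1] 0.222
```

The reference band values shipped in `growth_media()` live on the
energy scale of the calibration that produced them, so on this model's
scale they must be recalibrated before forecasting — that is the
default workflow:

```r
sweep <- run_stiffness_sweep(seed = 1)   # samples 1-70 kPa, calibrates
autoplot(sweep)                          # differentiation fractions
sweep$media                              # fitted lineage bands

islands <- run_island_sweep(media = sweep$media, seed = 1)
rock    <- run_rock_inhibition(media = calibrate_bands(
             sweep$conditions, reference_fractions("mixed")), seed = 1)
```

`run_stiffness_sweep()` prints, per condition, the solved `zeta`, the
`F_cyto` summaries and the observable means; with the defaults the
calibrated forecast at 30 kPa commits ~80% of cells to the osteoblast
lineage and leaves ~20% undifferentiated, the headline behaviour of
the model.

A command-line wrapper is provided in `exec/homeostat`
(`sample`, `forecast`, `sweep-stiffness`, `sweep-island`, `rock`,
`render` subcommands).

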