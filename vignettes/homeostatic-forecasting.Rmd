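---
title: "Homeostatic ensembles of cell shape and free-energy-based lineage forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic ensembles of cell shape and free-energy-based lineage forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(homeostat)
```

## The model

`homeostat` simulates single adherent cells (human mesenchymal stem
cells, hMSCs) as fluctuating two-dimensional bodies on elastic or
micro-patterned substrates, and forecasts their lineage commitment from
the distribution of their cytoskeletal free energy.

The physical picture is the *homeostatic ensemble*: a cell is an open
system that exchanges nutrients with its surroundings, and its
biochemical machinery holds the time-averaged copy number of every
internal species at a value independent of the environment. Writing
`G(j)` for the equilibrium Gibbs free energy of one morphological
microstate `j` (a full cell configuration: footprint shape plus the
equilibrated cytoskeleton), homeostasis pins the ensemble average,
`<G> = G_S`, where `G_S` is the free energy of the cell in suspension.
Maximizing morphological entropy under that constraint gives

    P_eq(j) = exp(-zeta * G(j)) / Z,

a Boltzmann-like distribution whose parameter `zeta` (inverse
*homeostatic temperature*) is solved from the constraint rather than
prescribed. The package samples this distribution by Markov chain Monte
Carlo, computes morphometric observables and the cytoskeletal
free-energy distribution, and maps the latter to lineage probabilities
through a band classifier.

### Microstates

A microstate's footprint is a smooth deformation `x = chi(X)` of the
reference circle of radius `R0` (nucleus radius `RN`, co-deforming):
an affine part (4 coefficients) plus polar harmonics of order 1-4 in
the boundary angle, radially weighted by `(r/R0)^n` for smoothness at
the origin — 20 coefficients in all. This basis reproduces circles,
ellipses and lobed spread shapes while keeping the Metropolis state
space small. Maps must be orientation-preserving on the quadrature grid
(`det F` bounded away from zero) and have a simple (non-self-intersecting) boundary;
proposals violating either, or leaving an adhesive island, are
rejected rather than penalized, so the energy model is only ever
evaluated on physical states.

### Gibbs free energy of a microstate

`G = F_passive + F_cyto + F_sub`, all normalized by `E_norm` (fJ).

**Passive elasticity.** Cytoplasm, nucleus and the lumped
membrane/microtubule background follow a compressible 2D Ogden model,

    Phi = (2 mu / m^2) (lambda_I^m + lambda_II^m - 2 - m log J)
          + (kappa / 2) (J - 1)^2,

with `mu = mu_c` in the cytoplasm and `mu_n` in the nucleus (smoothed
over `interface_w` so the traction model sees a continuous modulus).
The `-m log J` term makes `Phi >= 0` with equality only at the
identity — a plain two-term expansion would reward equibiaxial
compression, which is unphysical.

**Cytoskeleton.** At each point and fibre orientation `phi`, the
stress-fibre concentration `eta(x, phi)` is in chemical equilibrium
with a spatially uniform unbound pool `N_u` through a Langmuir-type
isotherm, `eta = eta_max N_u e^Psi / (1 + N_u e^Psi)`, with binding
advantage `Psi = (sigma Omega - mu_b0) / kT`. The fibre tension obeys
an isometric ceiling with shortening sensitivity,

    sigma = sigma_ceil * clamp(1 + beta * eps, 0, 1),

so stretched fibres hold their stall tension while shortening fibres
lose it. The ceiling itself depends on what the fibre pulls against
(a motor stalls at lower force on a compliant anchor):
`sigma_ceil = sigma_max * E_sub / (E_sub + E_half)` on an elastic
substrate, `sigma_max` on an effectively rigid island, and
`sigma_max * E_susp / (E_susp + E_half)` in suspension, where the only
anchor is the cell's own cortex. This stiffness feedback is what makes
polymerization rise and the cytoskeletal free energy fall with
substrate stiffness. Functional units per fibre follow the affine rule
`n = max(1 + eps, n_min)`, and global conservation
`N_u + (1/A_ref) ∫∫ eta n dphi dA = 1` is solved for the single scalar
`N_u`; the left side is strictly increasing in `N_u` with value `-1`
at zero, so the root in `(0, 1]` exists and is unique (asserted, and
solved by safeguarded Newton to residual `< 1e-12`). The free energy is

    F_cyto = (C_cyto / E_norm) [ N_u (ln N_u - 1)
             + (1/A_ref) ∫∫ eta n (ln(eta n / eta_max) - 1 - Psi) dphi dA ],

mixing entropy of the unbound pool plus bound-fibre standard free
energy minus the mechanical work of tension. Raising polymerization at
fixed strain strictly lowers `F_cyto`; the test-suite verifies this
rather than assuming it.

**Substrate.** The traction field follows from in-plane equilibrium of
the total (passive + active) Cauchy stress: the interior divergence,
computed spectrally (polynomial differentiation across the 24
Gauss-Legendre radial nodes, Fourier differentiation across the 36
angles), plus the free-edge stress resultant, which a
prescribed-kinematics model cannot equilibrate internally and which is
therefore transmitted through a peripheral adhesion band of width
`edge_w`. The field is then projected onto zero net force and torque
(the residual rigid-body imbalance of the discretization). An elastic
substrate is a Winkler foundation with modulus
`k = winkler_c * E_sub / R0`, storing `F_sub = 1/(2k) ∫ |T|^2 dA`;
a rigid island stores nothing. The Winkler choice preserves the one
property the forecasts rely on — the energy price of a unit traction
falls with substrate stiffness — at a small fraction of the cost of a
half-space Green's function, which remains a natural extension point.

### Parameter defaults

| parameter | default | units | role |
|---|---|---|---|
| `R0`, `RN`, `t0` | 20, 6, 1 | um | resting cell/nucleus radius, thickness |
| `mu_c`, `mu_n`, `m`, `kappa` | 1, 8, 2, 1 | kPa, -, kPa | passive Ogden elasticity |
| `sigma_max` | 240 | kPa | fibre stall tension (231 under ROCK inhibition) |
| `beta` | 3 | - | tension loss per unit shortening strain |
| `Omega`, `mu_b0`, `kT_hat` | 0.01, 1.3, 1 | 1/kPa, -, - | binding advantage scale |
| `eta_max`, `n_min`, `rho_f` | 1.5, 0.5, 0.05 | - | saturation, unit floor, fibre volume fraction |
| `E_half`, `E_susp` | 3, 0.7 | kPa | stall-tension compliance scale; suspension anchor |
| `C_cyto`, `E_norm` | 6000, 1000 | fJ | cytoskeletal energy scale; normalization |
| `winkler_c`, `interface_w`, `edge_w` | 2.5, 2, 2 | -, um, um | foundation constant, smoothing widths |

`R0` and `RN` are assumptions (the geometry of a representative hMSC),
not fitted values. The closure constants were fixed once, during model
design, so that the qualitative physics holds across the whole
condition range: every stiffness from 1 to 70 kPa admits a homeostatic
ensemble; polymerization rises with stiffness and saturates;
mean `F_cyto` falls monotonically with stiffness with well-separated
distributions; spreading, aspect ratio and tractions rise with
stiffness in mean and in spread; and a few-percent drop in `sigma_max`
moves `F_cyto` visibly while leaving morphology almost unchanged. They
are deliberately not re-tuned per experiment.

## Sampling

Metropolis proposals are independent Gaussians on the 20 shape
coefficients. During burn-in (default: 20% of the production length,
in ten segments) the per-coefficient scale adapts toward 25-35%
acceptance; the scales are then frozen so production sampling satisfies
detailed balance. Production chains are thinned (default x10). The
default desk-scale budget is 2e5 production steps for headline runs and
2-8e4 in the test-suite; chains are bit-reproducible from their seed.

`solve_zeta()` finds `zeta*` with `<G> = G_S` by stochastic
root-finding: pilot chains at successive `zeta` values are pooled, and
a multiple-importance-sampling (balance heuristic) estimate of
`<G>(zeta)` — monotone decreasing, since `d<G>/dzeta = -Var(G)` — is
root-found within a trust region of a factor 3 per iteration. A sliding
window over the most recent pilots discards pre-equilibration samples.
Convergence is declared when the update stabilizes and the pilot mean
is statistically consistent with `G_S`; the constraint is then
re-verified on the production chain and the gap recorded in the
diagnostics together with the acceptance rate, the integrated
autocorrelation time of `G` and a split-chain Rhat.

Two degenerate regimes are handled explicitly. If `G_S` lies below the
minimum reachable `G` (`zeta -> Inf`), that is a configuration error.
The opposite regime is a genuine feature of confinement: a mid-size
adhesive island (around 2000-5000 um^2 at the default cell size)
truncates exactly those strongly spread, high-energy states that an
unconfined ensemble uses to balance its deeply bound states, so even
`zeta -> 0` leaves `<G>` below `G_S`. `solve_zeta()` then returns the
maximum-entropy ensemble at a small floor (`zeta = 1e-3`), flags it
(`setpoint_unreachable`) and warns; sweep drivers keep going with the
condition marked non-converged. Observable trends across island areas
remain smooth and monotone through this regime, but the homeostatic
constraint itself is not met there — a known limitation of this
closure, not hidden by the software.

## Forecasting

Over the commitment window the cell visits `Nc` decorrelated
microstates (default 15), so the time-averaged cytoskeletal free energy
is Gaussian, `N(mu, sigma^2 / Nc)`, with `(mu, sigma)` the ensemble
statistics of `F_cyto`. A lineage `x` is chosen when the average falls
in its band `centre_x ± half_width_x`; raw probabilities are the
Gaussian band masses, normalized by `Z_L = max(1, sum Px)` with
`1 - sum(Px)/Z_L` remaining undifferentiated. The closed form equals
quadrature of the density over the band (tested to 1e-10).

Band values are scale-relative: they live on the energy scale of the
model that produced them. `growth_media()` and `mixed_media()` carry
the reference literature values (osteoblast 2.59 ± 0.14 and myoblast
1.87 ± 0.05 in growth medium; osteoblast 2.59 ± 0.37 and adipocyte
1.61 ± 0.44 in mixed medium, `Nc = 15`), but the default workflow
recalibrates on this package's own stiffness sweep with
`calibrate_bands()` — a least-squares fit of each lineage's
`(centre, half_width)` to observed differentiation fractions, with a
deterministic multistart and `half_width >= 0` enforced by a log
parameterization — and only then predicts new cue families
(island sizes, ROCK inhibition). That calibrate-on-one-cue,
predict-on-another protocol is the intended use.

`reference_fractions()` provides the calibration targets: for growth
medium, osteoblast commitment peaking near 0.8 at 30 kPa (about 20%
of cells remain undifferentiated there) and myoblast commitment
peaking near 0.8 at 10 kPa; for mixed medium, adipocytes favoured on
soft and osteoblasts on stiff substrates. The anchored points follow
the published measurements; intermediate values are smooth synthetic
interpolations and are documented as such.

Because the model's `F_cyto` distributions separate strongly across
stiffness relative to their width, the fitted bands come out narrow on
this package's scale, and island forecasts are close to all-or-nothing
outside a transition region; the mixed-media adipocyte band in
particular only fires under strong confinement. This is a recognizable
signature of the closure (environment-driven rather than purely
shape-driven binding), worth keeping in mind when comparing forecast
curves with measured fractions.

## The in-silico experiments

`run_stiffness_sweep()` (default 1, 3, 10, 30, 70 kPa),
`run_island_sweep()` (default 900-14400 um^2 plus the unpatterned
70 kPa reference) and `run_rock_inhibition()` (default
`A_p = 2725 um^2`, `sigma_max` 240 vs 231 kPa) reproduce the study
designs end to end: per condition they solve the homeostatic
constraint, sample, summarize observables, and forecast; results are
tibbles, optionally mirrored to CSV so figures regenerate from files.
The ROCK comparison runs both arms under common random numbers (same
seed), the standard paired design, so the contractility effect is not
confounded with chain noise; it reports per-observable L1 distances
between the treated and untreated densities — small for cell area,
aspect ratio and traction, large for `F_cyto` — and the forecast
shift.

Renders (`render_cell()`) rasterize a microstate at 0.5 um/pixel with
an actin channel proportional to the orientation-integrated fibre
content, an adhesion channel proportional to normalized traction
magnitude (restricted to the island where applicable), a nucleus mask
and a 20 um scale bar; identical inputs give identical bytes.

## What the simulator does and does not emulate

The generator reproduces, by construction: fluctuating cell footprints
with realistic area/aspect-ratio ranges, stiffness- and
confinement-dependent spreading, polymerization saturating with
stiffness, traction fields concentrated at the cell periphery, and the
cue-equivalence between stiffness and island size expressed through
`F_cyto`. It does not emulate: 3D morphology or cyclic loading, focal
adhesion or motor kinetics, viscoelastic substrates, nuclear
mechanotransduction beyond passive elasticity, gene-expression
dynamics, or measurement noise of real microscopy. Passing tests
therefore certify the internal consistency of the model and its
implementation, not biological fidelity beyond the qualitative trends
listed above.

## Numerical choices

- Quadrature: tensor Gauss grid, 24 radial x 36 angular points; 24
  fibre orientations on `[0, pi)`. Convergence was checked by doubling
  at design time; the identity-map area is exact to machine precision.
- Validity: maps must keep `det F > 0.02` everywhere on the grid.
  The margin (rather than bare positivity) excludes near-degenerate
  sliver states whose stress divergence produces unphysical traction
  spikes.
- Proposals are multi-scale: one step in ten uses a 4x larger Gaussian
  scale, which decorrelates confined (validity-limited) chains much
  faster at no cost to detailed balance.
- `density_l1()` evaluates both kernel estimates on a shared
  quantile-windowed grid (0.05%-99.95% of the pooled sample), so rare
  outliers cannot stretch the grid and wash out resolution where the
  probability mass lives.
- Protein conservation residual `< 1e-8` on every accepted state.
- Spectral differentiation for tractions; nucleus modulus and fibre
  availability smoothed over 2 um to avoid Gibbs ringing at the
  nucleus interface.
- Net traction force/torque removed by exact projection; pre-projection
  imbalance is part of the per-state diagnostics.
- Ties and degenerate cases: `zeta = 1` when `Var(G) = 0`; uniform
  unbound pool root unique by monotonicity; zero-width bands give zero
  probability; constant observables give zero variance and a spike
  density.
- Test-suite problem sizes: 3e4-step chains for the sweeps, 8e4 per
  ROCK arm, 1e5-step toy chains; the acceptance script uses 2e5-step
  production chains per condition. These are the package's desk-scale
  defaults; headline-quality studies should raise them (the chains
  report effective sample sizes so the cost/precision trade is
  visible).

## Known limitations

- The homeostatic setpoint is unreachable on mid-size islands (see
  above); those conditions are reported as maximum-entropy ensembles
  and flagged.
- The Winkler foundation ignores the non-local coupling of a true
  elastic half-space; `winkler_c` absorbs the difference only on
  average.
- Tractions come from prescribed kinematics plus projection, not a
  coupled cell-substrate equilibrium solve; the edge band width
  `edge_w` sets the peripheral traction scale.
- The energy normalization (`E_norm`, `C_cyto`) is internal; band
  values are not transferable across differently normalized models
  without recalibration.
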