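# biofilmadapt

Bacterial biofilms adapt to hydrodynamic stress: grown under orbital
shaking they reach higher attached-cell densities, make more extracellular
matrix, and end up orders of magnitude stiffer than statically grown
biofilms. `biofilmadapt` is an R toolkit for modelling and analysing that
adaptation. It is aimed at quantitative microbiologists and biophysicists
who want to reproduce the modelling chain end to end — population
dynamics, early colony growth, network mechanics — without any external
data: a synthetic-observation module emulates all the relevant
measurements.

## What is inside

**Two-compartment population model** (`simulate_population`,
`preset_params`, `fit_population`). Biofilm and planktonic compartments
each follow a logistic law whose growth rate and carrying capacity are
proportional to the local nutrient, μ(c) = μ_max·c/c_ref and
K(c) = K_max·c/c_ref, so the logistic term equals
μ(c)ρ − (μ_max/K_max)ρ², which stays finite when nutrients run out and
yields the death phase. Compartments exchange cells (attachment k⁺,
detachment k⁻) and nutrient (diffusion D); nutrient is consumed in
proportion to growth and self-degrades, so in a closed batch it can only
decrease. Shaking and static conditions differ *only* in
(k⁺, D, k⁻): (1, 1, 10⁻³) h⁻¹ versus (0.025, 0.05, 1) h⁻¹. Integration is
fixed-step RK4; fitting is bounded multi-start least squares on
24 h-normalised log10 counts.

**Run-and-tumble colony simulator** (`simulate_colony`,
`estimate_diffusion`, `growth_curve`). 2D spherocylinders run at
v = 0.2 μm/s, tumble as a Poisson process with mean run time
τ = 2D/v² = 35 s (so the long-time diffusion coefficient is
D = v²τ/2 = 0.7 μm²/s), interact via short-range repulsion plus a weak
0.2 ε depletion-attraction well, elongate linearly and divide at twice the
birth length every 1 h. Compiled (Rcpp) core with cell-list neighbour
search.

**Oscillatory-shear DPD network** (`build_shear_system`,
`add_crosslinks`, `oscillate`, `stress_ratio_curve`,
`evaluate_master_curve`). A coarse bacteria–polymer–solvent fluid
(biovolume composition 53:47 shaking, 72:28 static) is gradually
crosslinked and driven through Lees–Edwards sinusoidal shear; the
first-harmonic virial stress gives the stress response. The published
master curve relating the shaking/static stress ratio to the crosslink
ratio, 0.75x² + 4.4x − 1.14, is shipped as a reference curve.

**Rheology operators** (`extract_moduli`, `viscosity`, `detect_yield`).
Fourier projection of σ(t) against sin/cos(ωt) over whole cycles gives
G′ and G″, η = G″/ω, and a 10%-deviation-from-Hooke criterion locates the
yield strain γ_Y.

**Synthetic observations** (`generator_spec`, `gen_counts`,
`gen_coverage`, `gen_stress_strain`) and **IO/CLI** plumbing
(`read_timeseries`, `write_trajectory`, `run_cli`, plus an
`inst/exec/biofilm-adapt` Rscript wrapper).

## Worked example

```r
library(biofilmadapt)

tr_sh <- simulate_population(preset_params("shaking"), t_end = 96,
                             condition = "shaking")
tr_st <- simulate_population(preset_params("static"), t_end = 96,
                             condition = "static")
tr_sh
#> Biofilm population trajectory [shaking]: 9601 points, t in [0, 96] h (dt = 0.01 h)
#>   peak rho_b = 1.392 at t = 67.33 h; final (rho_b, rho_p) = (0.9234, 0.0009885)
tr_st
#> Biofilm population trajectory [static]: 9601 points, t in [0, 96] h (dt = 0.01 h)
#>   peak rho_b = 0.03634 at t = 67.47 h; final (rho_b, rho_p) = (0.02451, 0.903)
```

Both trajectories traverse exponential growth, saturation and decay; the
shaken biofilm peaks ~40-fold (1.6 log) above the static one because fast
attachment, fast nutrient diffusion and slow detachment funnel cells and
nutrient into the biofilm, while under static conditions detachment wins
and most cells stay planktonic (final rho_p = 0.90 vs 0.001 above).

```r
spec <- generator_spec("shaking",
                       times = c(8, 12, 24, 36, 48, 60, 72, 84, 96),
                       seed = 7)
fit <- fit_population(gen_counts(spec), n_restarts = 8, seed = 1)
fit
#> Population-model fit (8 restarts, seed 1)
#>   loss = 2.68278; converged: TRUE (8/8 restarts)
#>   k_plus   = 1.352 1/h  (bounds 0.0001..10)
#>   k_minus  = 0.0001 1/h  (bounds 0.0001..10)
#>   D_n      = 0.06783 1/h  (bounds 0.0001..10)
```

The attachment rate comes back near its true value 1 h⁻¹; k⁻ and D are
reported but structurally unidentifiable from normalised counts at this
noise level, and a mirror mode with k⁺ and k⁻ swapped fits almost as well
(see the methods vignette on identifiability) — under shaking only k⁺
should be interpreted quantitatively.

```r
detect_yield(gen_stress_strain(generator_spec("shaking", seed = 2)))
#> Yield detected at gamma_Y = 0.2187 (linear modulus 1007 Pa, threshold 10%)

evaluate_master_curve(c(6, 12))
#> [1]  52.26 159.66
```

The synthetic shaking biofilm yields at ~20% strain with a ~1 kPa Hookean
modulus, and the reference master curve returns stress-response ratios of
~50 at 6× crosslinks and ~150 at 12× — the measured stiffness contrast
between shaken and static biofilms at 24 h and 48 h.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantity from
scratch by running the installed package — the population doubling time of
the agent-based simulator, measured by growing a colony from a single
cell for six simulated hours in a dilute box and fitting log2 N(t)
against t — and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Repository layout

- `R/`, `src/` — implementation (base R + Rcpp cores)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/biofilm-hydrodynamic-adaptation.Rmd` — the methods vignette:
  model equations, parameter meanings and defaults, numerical choices,
  what the synthetic generators do and do not establish, known limitations
- `scripts/acceptance.R` — see above
- `inst/exec/biofilm-adapt` — command-line wrapper over `run_cli()`
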