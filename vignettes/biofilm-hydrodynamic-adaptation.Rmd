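---
title: "Modelling biofilm self-adaptation to hydrodynamic stress"
author: "biofilmadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biofilm self-adaptation to hydrodynamic stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(biofilmadapt)
```

Bacterial biofilms grown under hydrodynamic stress (orbital shaking) reach
higher attached-cell densities, produce more extracellular matrix, and are
mechanically far stiffer than biofilms grown statically. This package
implements the three computational engines with which those observations
can be modelled and analysed:

1. a **two-compartment population model** — nutrient-coupled logistic
   growth for the biofilm and planktonic phases, exchanging cells
   (attachment/detachment) and nutrient (diffusion) — with least-squares
   fitting of the transport rates to cell-count time series;
2. a **2D run-and-tumble agent-based simulator** of growing, dividing,
   weakly attracting rod-shaped bacteria for the first hours of colony
   growth;
3. a **coarse-grained DPD model** of a crosslinked
   bacteria–polymer–solvent network under oscillatory shear, together with
   **rheology operators** (storage/loss moduli, viscosity, yield strain)
   that apply equally to simulated and synthetic experimental records.

A synthetic-data module generates observation tables with the statistical
structure of the study's measurements, so that every analysis path is
testable end to end without external data.

## The population model

Each compartment (biofilm $b$, planktonic $p$) carries a cell density
$\rho$ and a nutrient concentration $c$. Growth follows a logistic law in
which both the specific growth rate and the carrying capacity are
proportional to the local nutrient (a Monod-type proportionality pushed
directly into the logistic equation):

$$\mu(c) = \mu_{\max}\,\frac{c}{c_{\mathrm{ref}}},\qquad
  K(c) = K_{\max}\,\frac{c}{c_{\mathrm{ref}}}.$$

The nutrient factor cancels in the quadratic term,

$$\mu(c)\rho\left(1 - \frac{\rho}{K(c)}\right)
  = \mu(c)\,\rho - \frac{\mu_{\max}}{K_{\max}}\rho^2,$$

so the death term stays finite as $c \to 0$: when nutrients are exhausted
the population decays quadratically. This single mechanism produces the
three observed regimes — exponential growth, saturation, decay — with one
parameter set. The full system is

$$
\begin{aligned}
\dot\rho_b &= \mu(c_b)\rho_b - \tfrac{\mu_{\max}}{K_{\max}}\rho_b^2
             + k^{+}\rho_p - k^{-}\rho_b,\\
\dot\rho_p &= \mu(c_p)\rho_p - \tfrac{\mu_{\max}}{K_{\max}}\rho_p^2
             - k^{+}\rho_p + k^{-}\rho_b,\\
\dot c_b   &= -\beta\,\mu(c_b)\rho_b - \delta c_b + D\,(c_p - c_b),\\
\dot c_p   &= -\beta\,\mu(c_p)\rho_p - \delta c_p - D\,(c_p - c_b),
\end{aligned}
$$

integrated by classical fixed-step RK4 (`simulate_population()`, default
$dt = 0.01$ h, at least 100 steps per fastest time constant). Nutrient is
consumed proportionally to the *gross growth rate* ($-\beta\mu(c)\rho$),
not to the population: consumption stops when growth stops, and in a
closed batch the total nutrient can only decrease — a property the tests
assert along every trajectory.

Hydrodynamic conditions differ **only** in the three transport rates:

| condition | $k^{+}$ (1/h) | $D$ (1/h) | $k^{-}$ (1/h) |
|-----------|--------------|-----------|---------------|
| shaking   | 1            | 1         | $10^{-3}$     |
| static    | $25\times10^{-3}$ | 0.05 | 1             |

Shaking enhances attachment and nutrient diffusion and suppresses
detachment (stronger adhesion under stress).

### Calibrated defaults and their limits

The remaining parameters are not published and are calibrated, not
measured: $\mu_{\max} = \ln 2$ (dilute doubling time of exactly 1 h at
the reference nutrient), $K_{\max} = 10$, $\beta = 0.05$,
$\delta = 0.005$ 1/h, initial state $(\rho_b, \rho_p, c_b, c_p) =
(0, 10^{-4}, 0.3, 0.3)$ in densities normalised to the 24 h biofilm count
and dimensionless nutrient with $c_{\mathrm{ref}} = 1$. The initial
nutrient below $c_{\mathrm{ref}}$ encodes growth at sub-reference
conditions (rich medium at 20 °C is well below the optimum) and stretches
the exponential phase so the population peaks fall in the experimentally
observed 48–72 h window.

One limitation is structural and worth stating plainly: because the two
conditions share every non-transport parameter, the peak *time* is set by
the common exponential phase. The transport rates move the peak *height*
(the shaking biofilm peaks $\sim$40-fold — 1.6 log — above the static
one) but cannot separate the peak times; the experimentally observed
early static plateau versus late shaking maximum is not reproducible
within this model family. The package therefore asserts the regime shape
and the height ordering, not a timing difference.

Near extinction the fixed-step integrator can undershoot zero; any
negative component is clamped to zero and a warning is emitted, which
preserves the physical state space without switching integrators.

### Fitting and what is identifiable

`fit_population()` minimises the sum of squared residuals between
log10 observed counts and log10 model densities, both normalised to their
own 24 h value (CFU data span decades and are presented normalised, so
the fit lives on that scale). The optimiser is bounded multi-start
L-BFGS-B in log10 parameter space: each rate in $[10^{-4}, 10]$ 1/h
(two decades of margin around both presets), 16 Latin-hypercube restarts
by default, fully seeded.

The fitting machinery is this package's addition — whether the original
trajectories were fitted or hand-tuned is not stated anywhere — and its
honest behaviour is characterised in the tests: from noisy synthetic
counts (sd 0.1 log10, ten replicates) the dynamically dominant rate of
each condition — $k^{+}$ under shaking, $k^{-}$ under static — is
recovered with median relative error around 40%, but $k^{-}$ at its
shaking value ($10^{-3}$ 1/h moves 0.1% of the biofilm per hour), the
static $k^{+}$, and $D$ above $\sim$0.05 1/h are *structurally
unidentifiable* from normalised count data — the loss surface is flat in
those directions at realistic noise. Worse, normalising each series to
its own 24 h value makes the two compartment roles nearly symmetric: a
mirror mode with $k^{+}$ and $k^{-}$ swapped fits almost equally well
and captures the best-of-restarts fit for roughly a quarter of noise
draws, so even the qualitative $k^{+}$-vs-$k^{-}$ ordering is recovered
in only ~70–80% of data sets. Deeper multi-start search makes this
*more* frequent, not less — the symmetry lives in the likelihood, not in
the optimiser. Dropping the planktonic series degrades $k^{+}$ recovery
further (widened spread), which the tests assert as such rather than
hiding.

## The run-and-tumble colony simulator

Early biofilm growth (first ~12 h, a few hundred cells on a surface) is
simulated as 2D spherocylinders that

* **run** at $v = 0.2$ μm/s along their axis and **tumble** as a Poisson
  process, redrawing the orientation uniformly;
* **interact** through a split Lennard-Jones potential on the minimum
  distance between body segments: full-strength repulsion (scale
  $\varepsilon$) continued by an attractive tail scaled to well depth
  $0.2\,\varepsilon$ — the effective depletion attraction induced by the
  excreted polymers;
* **grow** linearly from birth length $l_0$ to $2 l_0$ over
  $t_{\mathrm{dup}} = 1$ h (the measured duplication time at 20 °C) and
  then split into two end-to-end daughters with a small orientation
  perturbation (sd 0.1 rad, preventing artificial straight chains).

The tumble statistics are not published; only the pair
($D \sim 0.7$ μm²/s, $v \sim 0.2$ μm/s) is. For complete orientation
decorrelation in 2D, $D = v^2\tau_{\mathrm{run}}/2$, which fixes
$\tau_{\mathrm{run}} = 2D/v^2 = 35$ s — the package's default, verified
by the mean-squared-displacement estimator (`estimate_diffusion()`),
which also reports the ballistic-to-diffusive crossover at
$4D/v^2 = 70$ s.

Numerical choices: overdamped first-order dynamics (bacterial Reynolds
number is effectively zero; the mobility default 0.1 μm²/(ε·s) absorbs
the friction constant); body dimensions $l_0 = 2$ μm, $w = 0.8$ μm
(rod-sized, typical of pseudomonads; not published values); timestep
0.05 s. Per-step displacements are capped at 0.25 σ so that the stiff
core cannot overshoot. Instantaneous tumbles can momentarily *cross* two
rods in a dense microcolony — an artefact of redrawing the orientation in
place — and division inserts daughters in near-contact; both produce
transient deep overlaps that the capped repulsion resolves within a few
steps (crossed pairs are separated along their centre line, where the
segment-distance direction degenerates). The steric "timestep too large"
error therefore fires only on *persistent* overlap below half a width,
which is what actually signals an unstable step size.

Division is deterministic by default (`growth_cv = 0`): the cell count
from a single seed is exactly $2^{\lfloor t/t_{\mathrm{dup}}\rfloor}$
regardless of motility or attraction, which is also why the early growth
curve is independent of the hydrodynamic condition in this model. A
lognormal per-cell duplication-time variability (`growth_cv`) is exposed
for desynchronised colonies but is not part of the default world.

## The sheared bacteria–polymer network

The mature biofilm under shear is coarse-grained as a standard DPD fluid
(reduced units: density 3, like-pair repulsion 25, cutoff 1, $k_BT = 1$,
friction 4.5 with the random force tied by fluctuation–dissipation,
velocity-Verlet at $dt = 0.02$). Bead types are solvent, polymer
(bead-spring chains of 10) and bacteria, rendered as short stiff bead
rods (5 beads, nearest- plus next-nearest-neighbour springs) rather than
rigid bodies — at these bead counts a stiff bonded rod is
indistinguishable from a rigid one under shear and needs no rigid-body
integrator. The non-solvent fraction is composed according to the
measured biovolume ratios: bacteria:polymer 53:47 (shaking) and 72:28
(static).

`add_crosslinks()` grows the network gradually: harmonic links between
randomly chosen beads of *different* non-solvent molecules within a
capture radius of 1.2 cutoffs, placed in batches with unsheared
relaxation in between. Oscillatory simple shear
$\gamma(t) = \gamma_0\sin\omega t$ is imposed through Lees–Edwards
boundaries (position and velocity remapped at the crossing with the
instantaneous strain offset), and the off-diagonal virial stress with
flow-subtracted kinetic part is recorded each step; the first cycle is
discarded as transient. The "stress response" reported for the master
curve is the **first-harmonic amplitude** of $\sigma_{xy}$, i.e.
$|G^*|\gamma_0$ — the lock-in definition; whether the original analysis
used $G'$, $|G^*|$ or peak stress is not stated, so this choice is
declared here.

What this reconstruction reproduces, and what it cannot: the storage
modulus grows monotonically with crosslink count, the shaking/static
stress-response ratio grows with the crosslink ratio, momentum is
conserved to machine precision, and the thermostat holds the temperature
within 5% exactly when fluctuation–dissipation is honoured (and drifts
when deliberately violated). The published quadratic master curve
$0.75x^2 + 4.4x - 1.14$ is shipped as a reference
(`evaluate_master_curve()`) and is *not* refitted from scratch — the
original model's full parameterisation was never published. Two further
honest deviations: with permanent harmonic
crosslinks the network's nonlinearity is geometric strain *hardening*,
not yield; reproducing the observed softening and the "static stays
linear to larger strain" ordering would need breakable or
finite-extensibility links, which the declared design (plain harmonic
links) excludes. Yielding stress–strain curves are instead provided by
the synthetic generator, where the yield strain is an input.

## Rheology operators

For $\gamma(t) = \gamma_0\sin\omega t$ a linear material responds with
$\sigma(t) = \gamma_0[G'\sin\omega t + G''\cos\omega t]$.
`extract_moduli()` recovers $G'$ and $G''$ by Fourier projection over
whole cycles (requiring at least two, rejecting non-integer spans) and
the viscosity as $\eta = G''/\omega$. The source formalism states
$\eta = G''/\omega$ in its methods and a product form once in passing;
the quotient is the dimensionally correct choice for Pa·s and is used
throughout. Projection is applied to the raw record — no smoothing —
because whatever filtering the rheometer firmware applied is unknown.

`detect_yield()` operationalises the visually identified yield point: fit
the Hookean slope through the lowest amplitudes (at least three) and
report the smallest amplitude deviating from it by more than 10%
(configurable). On synthetic curves this recovers the measured yield
strains — $\gamma_Y \approx 0.2$ for shaking, $\approx 1.0$ for static —
to within one amplitude-grid step.

## The synthetic-data generators

`generator_spec()` fixes a stated world per condition and every generator
is a pure function of (spec, seed):

* **counts** — the ODE trajectory sampled at the experimental grid
  (24/48/72/96 h, 10 replicates), multiplied by lognormal noise
  (Gaussian sd 0.1 on log10 — a declared stand-in matched by eye to
  plate-count error bars, not a published value);
* **coverage** — a logistic rise (midpoint 24 h, width 8 h) to a
  condition-dependent cap (55% shaking, 35% static) with a mild decline
  after 60 h (submerged-area detachment), truncated-Gaussian noise,
  clamped to [0, 100]; the zero-noise shaking curve peaks inside the
  observed 48–72 h window;
* **stress–strain** — Hookean up to the condition's yield strain with the
  published modulus magnitudes ($G' \sim 1$ kPa shaking, $\sim 10$ Pa
  static), then a plastic plateau with mild power-law softening
  (exponent 0.1) and 2% multiplicative noise.

A green test against these generators establishes that the *operators*
are correct and the inference contracts hold in the stated world; it does
not validate the noise model against real plate counts, nor the
coverage/stress functional forms beyond their qualitative shape.

## Worked example

```{r example}
tr_sh <- simulate_population(preset_params("shaking"), t_end = 96,
                             condition = "shaking")
tr_st <- simulate_population(preset_params("static"), t_end = 96,
                             condition = "static")
tr_sh
tr_st
```

```{r plot}
plot(tr_sh)
```

```{r fit-example}
spec <- generator_spec("shaking", times = c(8, 12, 24, 36, 48, 60, 72, 84, 96),
                       seed = 7)
fit <- fit_population(gen_counts(spec), n_restarts = 8, seed = 1)
fit
```

```{r rheo-example}
curve <- gen_stress_strain(generator_spec("shaking", seed = 2))
detect_yield(curve)
evaluate_master_curve(c(6, 12))
```

## Known limitations

* The population model is well-mixed per compartment: no spatial
  structure, no explicit matrix production, no stochastic
  (demographic-noise) dynamics.
* Peak-time separation between conditions is outside the model family's
  reach (see above); the fitted transport rates other than $k^{+}$ are
  reported but should not be interpreted quantitatively.
* The colony simulator is 2D, torque-free (orientation changes only by
  tumbling and division noise), without hydrodynamic interactions or
  explicit polymer particles.
* The DPD network uses community-standard water-like parameters, not the
  original (unavailable) parameterisation; its stress scale is in reduced
  units and only ratios and orderings are meaningful. Its harmonic
  crosslinks harden rather than yield.
```
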