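---
title: "Methods: temperature-dependent mixotroph evolution with adaptive dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-dependent mixotroph evolution with adaptive dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixoevolve)
```

## The ecological model and its assumptions

`mixoevolve` models a constitutive mixotroph `M` and its bacterial prey
`B` in a well-mixed water column, with depth-integrated densities
(cells cm^-2^):

$$\frac{dM}{dt} = \left[P(\theta, z, I_{in}, T, M) + G(\theta, T, B) - l\right] M,
\qquad
\frac{dB}{dt} = \left[r\left(1 - \frac{B}{K_B}\right) - \alpha(\theta, T) M\right] B.$$

The structural assumptions, each of which shapes what the results can and
cannot say:

* **Photosynthesis** saturates with light and is averaged over an
  exponentially attenuating light profile, so per-capita photosynthetic
  growth declines with the population's own density (self-shading):
  $P = \frac{\rho(\theta,z,T)}{kM}\ln\frac{h + I_{in}}{h + I_{in}e^{-kM}}$.
  Light competition is therefore purely intraspecific; nutrients are
  never limiting.
* **Grazing** is a Type-I (linear) functional response $G = b\,\alpha B$:
  adequate at the bacterial densities modelled, but with no handling-time
  saturation.
* **Thermal scaling is linear** in temperature above a per-metabolism
  threshold, with heterotrophy more temperature-sensitive than
  photosynthesis ($m_\alpha > m_\rho$). Linearity is a deliberate
  simplification: it guarantees that any nonlinearity in the evolutionary
  response is generated by ecological feedback (prey depletion,
  self-shading), not by curvature built into the physiology. Real thermal
  reaction norms are unimodal; nothing here represents enzyme denaturation
  at an upper critical temperature, so behaviour far above ~33 °C is an
  extrapolation of the linear regime, not a physiological prediction.
* **Prey are evolutionarily and thermally inert**: `r` and `K_B` are
  constants. Bacterial thermal responses and co-evolution are out of
  scope.
* **The trade-off** between investments is
  $\rho_0(\theta, z) = \rho_{max}(1 - \theta^{2^z})^{2^{-z}}$, a one-parameter
  family pinned to $\rho_{max}$ at $\theta = 0$ and 0 at $\theta = 1$.
  `z` is the single knob controlling whether intermediate strategies are
  cheap (`z > 0`), neutral (`z = 0`) or expensive (`z < 0`).

## Parameters

Defaults (see `mixo_params()`) describe a marine *Ochromonas*-like
mixotroph:

| symbol | default | units | role |
|---|---|---|---|
| `rho_max` | 1 | d^-1^ | max photosynthetic rate |
| `alpha_max` | 1.5e-9 | cm^2^ d^-1^ cell^-1^ | max attack rate |
| `b` | 0.15 | cell~M~ cell~B~^-1^ | prey-to-mixotroph conversion |
| `K_B` | 1e8 (swept to 3e8) | cell cm^-2^ | prey carrying capacity |
| `r` | 0.693 | d^-1^ | prey growth rate (doubling per day) |
| `h` | 250 | µmol quanta m^-2^ s^-1^ | light half-saturation |
| `I_in` | 100 (swept to 150) | µmol quanta m^-2^ s^-1^ | incident light |
| `k` | 5e-7 | cm^2^ cell^-1^ | per-cell absorbance |
| `l` | 0.05 | d^-1^ | mortality |
| `m_rho`, `T0_rho` | 0.1, 3 | °C^-1^, °C | photosynthesis thermal slope / floor |
| `m_alpha`, `T0_alpha` | 0.25, 9 | °C^-1^, °C | phagotrophy thermal slope / floor |
| `z` | none (must be chosen) | – | trade-off curvature |

With these coefficients both thermal multipliers equal exactly 1 at
13 °C, which makes 13 °C the natural reference temperature for the
static-lineage comparisons. The canonical analysis grid is 13–33 °C in
1 °C steps (the scenario loader accepts any range; thermal floors make
9–13 °C meaningful too, and `analysis: T_min: 9` in a scenario file
selects it). An exponential thermal variant
(`thermal_response: "exponential"`, multiplier $e^{m(T-13)}$ anchored to
1 at 13 °C) is included purely as a sensitivity switch; it is not
calibrated against anything.

## Numerical choices

* **Removable singularity at `M = 0`.** The depth-averaged light factor
  is 0/0 at `M = 0`; below `kM < 1e-8` the analytic limit
  $I_{in}/(h + I_{in})$ is substituted. The switch point is far below one
  cell per cm^2^, so it never interacts with ecology.
* **Equilibria.** The prey nullcline
  $B(M) = \max(0, K_B(1 - \alpha M / r))$ is substituted into the
  mixotroph per-capita growth, and the resulting 1-D condition is solved
  by a sign scan on a logarithmic grid (240 points over
  $10^{-2}$–$10^{12}$ cells cm^-2^, expanded 1000-fold up to twice if no
  bracketing is found) followed by Brent refinement to a relative
  tolerance of 1e-10. Per-capita residuals at reported equilibria are
  at the 1e-12 d^-1^ level or better, which is what keeps the
  invasion-fitness diagonal within 1e-8 of zero.
* **Nonviability clipping.** If a rare invader cannot grow in the empty
  environment (growth at `M -> 0`, `B = K_B` non-positive) the state is
  clipped to `M* = 0`, `B* = K_B`. Viability is therefore *exactly*
  equivalent to the sign of `empty_environment_growth()`, a property the
  tests enforce.
* **Multiple roots.** All positive roots are reported; the largest
  locally stable root (finite-difference Jacobian, eigenvalue test) is
  designated the resident equilibrium, matching what forward dynamics
  from high density converge to. In the canonical scenarios the reduced
  growth condition is monotone in `M` and a single root arises, but the
  tie-break is documented in the output (`roots`) so users can audit it.
  A `B* = 0` (prey-extinct) root is reported with a warning; it lies
  outside the regime analyzed.
* **Derivatives of fitness.** Selection gradients use a central
  difference with step 1e-5 in trait units (one-sided at the
  boundaries); fitness curvature for stability classification uses step
  1e-3; curvature magnitudes below 1e-6 are treated as zero. Below these
  scales fitness differences are dominated by equilibrium-solver noise.

## The adaptive-dynamics layer

Ecology is assumed fast relative to mutation: each resident reaches its
equilibrium before the next rare mutant appears, and evolution is a
trait-substitution sequence. Invasion fitness of mutant `theta_mut`
against resident `theta_res` is the mutant's per-capita growth in the
resident-set environment `(M*, B*)`.

`trait_substitution()` steps the resident by 1e-3 in the direction of the
selection gradient, accepting a step only if the mutant's invasion
fitness is positive; near an attractor the step is halved down to 1e-4,
and the ascent terminates when a local scan at 1e-4 resolution finds no
mutant improving fitness by more than 1e-10 d^-1^. `ess_curve()`
continues the attractor across a temperature grid, warm-starting each
temperature from the previous attractor so that branch identity is
preserved; for `z < 0` two branches are tracked (from 0.05 and 0.95) to
expose the specialist's bistability.

Two situations need documented conventions:

* **Extinct residents.** A nonviable resident sets no environment, and
  every nearby mutant also fails to invade the empty environment, so the
  literal replace-if-invading rule would freeze any lineage that starts
  in the nonviable region. The package instead lets such a lineage
  hill-climb the empty-environment growth surface (a step is accepted if
  it increases that growth). This reproduces the specialist's
  full-phagotrophy branch as an attractor that is *reported nonviable*
  below its threshold temperature, rather than silently dropped, and
  matches the gray-region semantics of the invasibility plots.
* **The flat landscape at `z = 0`.** With a linear trade-off, fitness is
  linear in the mutant trait, so at an interior gradient zero *every*
  mutant has exactly zero invasion fitness. Such points are classified
  `neutral` (curvature magnitude below tolerance) and used as the
  attractor for continuation purposes; whether the neutrality would
  resolve into coexistence of many strategies is deliberately left
  unexplored.

Singular points are located by scanning the gradient on a 201-point grid
and refining sign changes by bisection, then classified by the standard
second-order conditions: evolutionary stability from the sign of the
fitness curvature in the mutant direction, convergence stability from
the slope of the gradient through the crossing. Convergence-unstable
points are repellers; convergence-stable, evolutionarily unstable points
are branching points. Branching is detected and reported but never
simulated onward — no dimorphic dynamics. For the canonical specialist
(`z = -1`) the interior singular point is a repeller throughout the
13–33 °C range; a branching point appears only when the linear thermal
extrapolation is pushed to extreme temperatures (the classification
machinery is exercised there in the tests, at 100 °C, well outside the
physiologically meaningful range).

Boundary traits are reported as attractors whenever the one-sided
gradient points into the boundary. Pairwise invasibility plots
categorize each (resident, mutant) cell by the sign of fitness, with a
1e-8 d^-1^ tolerance so the identically zero diagonal is never
classified as invasion.

## The carbon-cycling comparison

`carbon_cycling_comparison()` contrasts an *evolving* lineage (investment
at `theta_ESS(T)`) with a *static* one (investment frozen at the
reference-temperature attractor, 13 °C by default) and records the
population growth components at equilibrium, `P·M*` (carbon-fixation
proxy) and `G·M*` (remineralization proxy). Fluxes are left in
cell cm^-2^ d^-1^ — they are growth-rate components used as proxies, not
a carbon mass budget. At any interior equilibrium `P + G = l`, so the two
fluxes always sum to `l·M*`; the tests assert this identity to 1e-6
relative. For `z < 0` both specialist branches are emitted; evolution
moves neither, so evolving and static records coincide on each branch by
construction.

## Problem sizes and determinism

Everything is deterministic: no Monte-Carlo enters anywhere, and two runs
of any command produce byte-identical outputs. The study-scale analyses
(21-temperature continuations, 201-point PIPs and gradient scans) each
run in seconds on one core; the test suite uses the same grids with a
few coarser sweeps (41-point PIPs, 4 °C steps) where only topology is
being asserted. The ODE-integration cross-check in the tests
(`deSolve::lsoda` run to a per-capita residual below 1e-9 d^-1^) is an
independent oracle for the root-finding solver, never a substitute
for it.

## Known limitations

* Linear thermal responses extrapolate without bound; conclusions at
  temperatures far above the calibrated range reflect the extrapolation.
* Evolutionary endpoints only: the trait-substitution sequence assumes
  evolution fast enough to track the environment, and reports attractors,
  not transients or rates of adaptation.
* No post-branching (dimorphic) dynamics, no mutation-limited stochastic
  dynamics, no plasticity, no seasonal or fluctuating forcing.
* Single mixotroph lineage and single prey; no competition between
  trade-off types, no co-evolution, and no explicit carbon-mass or
  export-flux accounting.
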