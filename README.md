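# mixoevolve

Eco-evolutionary analysis of temperature-dependent mixotrophy.

Constitutive mixotrophs are single-celled plankton that keep their own
chloroplasts yet also eat bacteria. Because heterotrophic rates accelerate
faster with temperature than photosynthetic rates, ocean warming shifts
the payoff between the two metabolisms — and over many generations the
*investment strategy* itself evolves. `mixoevolve` couples a two-species
population model of a mixotroph and its bacterial prey to the adaptive
dynamics framework, and asks where evolution drives the mixotroph's
phagotrophic investment as temperature, light and prey availability
change, and what that does to the population's carbon fixation and
remineralization at equilibrium.

The package is aimed at theoretical ecologists and modellers: everything
is deterministic, desk-scale, and scriptable from R or a command line.

## The model

A mixotroph population `M` (cells cm⁻², depth-integrated for a well-mixed
water column) grows by photosynthesis and by grazing on logistically
growing bacteria `B`, and dies at rate `l`:

    dM/dt = [ P(θ, z, I_in, T, M) + G(θ, T, B) − l ] · M
    dB/dt = [ r (1 − B/K_B) − α(θ, T) · M ] · B

Photosynthesis saturates with light (half-saturation `h`) and is averaged
over depth with self-shading (per-cell absorbance `k`, incident light
`I_in`):

    P = ρ(θ, z, T)/(k M) · ln[ (h + I_in) / (h + I_in e^{−kM}) ]

Grazing is a Type-I functional response, `G = b α(θ, T) B`. Both
metabolic capacities scale linearly with temperature above a
metabolism-specific threshold, with heterotrophy the more
temperature-sensitive of the two:

    α(θ, T) = α_max · θ · max(0, m_α (T − T0_α))
    ρ(θ, z, T) = ρ_0(θ, z) · max(0, m_ρ (T − T0_ρ))

The trait under selection is the phagotrophic investment `θ ∈ [0, 1]`,
constrained by a photosynthesis–phagotrophy trade-off whose curvature is
set by a shape parameter `z`:

    ρ_0(θ, z) = ρ_max (1 − θ^(2^z))^(2^(−z))

`z = 1` (convex) describes a "generalist" that keeps both metabolisms
cheaply, `z = −1` (concave) a "specialist" for whom any intermediate
strategy is expensive, and `z = 0` a linear trade-off.

Evolution is modelled with adaptive dynamics: a rare mutant `θ_mut`
invades the resident's equilibrium environment with fitness

    λ(θ_mut, θ_res) = ρ(θ_mut, z, T)/(k M*) · ln[(h + I_in)/(h + I_in e^{−k M*})]
                      + b α(θ_mut, T) B* − l ,

and trait substitution proceeds until an evolutionarily stable investment
`θ_ESS` is reached. The package computes invasion fitness, selection
gradients, pairwise invasibility plots (with the nonviable-resident "gray
region" semantics), classified singular strategies (ESS / branching point
/ repeller / neutral), `θ_ESS(T)` continuations, and evolving-vs-static
comparisons of the equilibrium population growth components `P·M*`
(carbon-fixation proxy) and `G·M*` (remineralization proxy).

A note on units: densities are depth-integrated (cells cm⁻²), light is in
µmol quanta m⁻² s⁻¹ and absorbance in cm² cell⁻¹; the parameter set is
used exactly as stated, with no unit conversion between the light and
area scales — it is internally consistent only taken at face value.

## Worked example

```r
library(mixoevolve)
p <- canonical_params("generalist")   # z = 1, K_B = 1e8, I_in = 100

find_resident_equilibrium(theta = 0.3, T = 18, p)
#> Resident equilibrium (theta = 0.3, T = 18 degC)
#>   M* = 2.7189e+07 cells/cm^2, B* = 9.60276e+07 cells/cm^2 [interior]
#>   viable: TRUE, locally stable: TRUE, per-capita residual = 2.78e-17

ess_curve(p, T_grid = seq(13, 33, by = 4), theta_init = 0.5)
#>    T branch theta_ess viable   M_star   B_star
#> 1 13   main    0.4435   TRUE 15006789 98559413
#> 2 17   main    0.8016   TRUE 31514553 89063700
#> 3 21   main    0.9032   TRUE 56433213 66901371
#> 4 25   main    0.8916   TRUE 65378347 49531313
#> 5 29   main    0.8536   TRUE 67179584 37938861
#> 6 33   main    0.8016   TRUE 67538581 29689705
```

At 18 °C a resident investing 30 % in phagotrophy coexists with its prey
at an interior, locally stable steady state. The continuation shows the
generalist's evolutionarily stable investment rising steeply with warming
(0.44 at 13 °C to 0.90 at 21 °C) and then *falling* again at high
temperature: grazing has depleted the bacteria (`B*` drops from ~9.9e7 to
~3.0e7 cells cm⁻²), so photosynthesis regains the selective edge. The
attractor is a genuine ESS:

```r
find_singular_points(18, p, grid_n = 101)[, c("theta_star", "classification")]
#>   theta_star classification
#> 1      0.851            ESS
```

The same analyses are exposed as a CLI:

```sh
Rscript inst/cli/mixoevolve.R fixtures --dir scenarios   # canonical YAMLs
Rscript inst/cli/mixoevolve.R ess --config scenarios/generalist.yaml --out ess.csv
Rscript inst/cli/mixoevolve.R pip --z -1 --temp 18 --n 201 --out pip.csv
Rscript inst/cli/mixoevolve.R carbon --z 0 --out carbon.csv
```

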