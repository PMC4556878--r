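# agarfilm

Growth kinetics of a bacterial biofilm on an agar plate, as a small,
fully tested simulator. The target system is a *Bacillus subtilis* colony
spotted on an MSgg agar plate: the colony is fed only from below, by
nutrient diffusing out of the agar reservoir, and its fate is set by the
race between biomass build-up and reservoir exhaustion. The package is
aimed at people who model microbial colonies — it provides the
zero-dimensional (thickness-only) model, a stiff integrator front end
with event detection, a parameter-sweep engine for sensitivity
directions, and the Beer–Lambert optical-density calibration used to turn
top-view transmission images into thickness profiles.

## The model

The film is a homogeneous slab of active biomass (volume fraction `f`),
inactive biomass (`f̄`), and water (`ε_a`), with `f + f̄ + ε_a = 1`. Four
coupled balances govern thickness `L`, active fraction `f`, the in-film
nutrient concentration `S`, and the agar reservoir concentration `S_a`
(units fixed to cm, mg, day; `μ = S/(K+S)` is the Monod factor):

    df/dt   = Y·V_T·μ·f·(1 − f/(1−ε_a)) − b·f
    dL/dt   = f·L·Y·V_T·μ / (1−ε_a)
    dS/dt   = D/(L_a·L)·(S_a − S) − V_T·μ·(ρ·f + S·Y·f/(1−ε_a))
    dS_a/dt = −σ·D·(S_a − S)/(L_a·V_a)

Growth converts nutrient to biomass at yield `Y`; active biomass
inactivates at rate `b`; nutrient crosses the laminar sublayer of
thickness `L_a` by Fick's first law. Two closed forms follow from the
structure and serve as built-in oracles: the nutrient-equivalent mass
`S_a·V_a + S·σ·L + ρσ(1−ε_a)L/Y` is exactly conserved, which fixes the
asymptotic thickness `L(0) + Y·(S_a(0)·V_a + S(0)·σ·L(0))/(ρσ(1−ε_a))`,
and while nutrient is abundant the active fraction approaches the
logistic equilibrium `(1−ε_a)·(1 − b/(Y·V_T))`.

The calibration module inverts the Beer–Lambert law `OD = h/λ`
(`OD = −log₁₀(I/I₀)`): the attenuation length `λ` is fitted by least
squares through the origin from paired top-view transmission and
side-view height profiles, and a synthetic profile generator provides
such pairs with known ground truth.

## Worked example

```r
library(agarfilm)

sim <- simulate_biofilm(horizon = 10)   # reference preset, 10 days
summary(sim)
```

```
Biofilm growth simulation over [0, 10] days (2001 states)
  final state: L = 0.0626 cm, f = 0.02094, S_a = 1.849e-22 mg/cm^3
  conserved-mass drift: 5.68e-09 (relative)
  conservation-law final thickness: 0.0626 cm
  event peak_active_fraction   t = 0.9636    value = 0.192152  [max f by continuous refinement of the saved grid]
  event substrate_depleted     t = 1.641     value = 0.15  [first S_a < 0.01 x S_a(0)]
  event steady_state_reached   t = 2.745     value = 0.0625989  [first (dL/dt)/L < 0.0001 per day]
```

Reading this: the film grows from 1 µm to a steady 0.06 cm (0.0626 cm is
the conservation-law ceiling, approached to within 0.002%); the active
fraction peaks at 0.19 just before day 1, under its analytic ceiling of
0.1923; the agar is down to 1% of its initial 15 mg/cm³ at day 1.6; and
thickness growth has effectively stopped (relative rate below 10⁻⁴/day)
by day 2.7. The conserved-mass drift of 6×10⁻⁹ is the integration
diagnostic. Sensitivity directions come from sweeps, e.g.

```r
run_sweep(sweep_spec("rho", c(150, 300, 600)))$results$final_thickness
#> [1] 0.12510 0.06260 0.03135     # denser biomass packs into a thinner film
```

and the calibration round-trip:

```r
pr  <- synthesize_profile("plateau_rim", n = 200, lambda = 0.02,
                          noise_level = 0.05, seed = 42)
fit_attenuation_length(pr)
#> Beer-Lambert attenuation fit: lambda = 0.0200009 cm (200 points, residual RMS 0.000558 cm)
```

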