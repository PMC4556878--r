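---
title: "A four-variable model of biofilm growth on an agar plate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-variable model of biofilm growth on an agar plate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agarfilm)
```

## The model and its assumptions

A colony growing on an agar plate is fed only from below: nutrient
diffuses out of the agar, across a thin laminar sublayer, into the film.
`agarfilm` implements the simplest closed description of that situation.
The film is treated as a laterally homogeneous slab of area `sigma`
sitting on an agar reservoir of volume `V_a`, composed of active biomass
(volume fraction `f`), inactive biomass (`f_bar`), and water (`eps_a`),
with `f + f_bar + eps_a = 1`. Four ordinary differential equations track
thickness `L`, active fraction `f`, in-film nutrient `S`, and reservoir
nutrient `S_a`; see `?biofilm_rhs` for the right-hand side.

The assumptions worth keeping in mind:

* **Zero spatial dimension.** Thickness is a scalar; there is no radial
  or azimuthal structure, no wrinkles, no phenotype rings. Real colonies
  are visibly inhomogeneous in both directions — this model averages all
  of that away and should be read as a statement about column-averaged
  growth.
* **Monod uptake.** Consumption is `V_T * S/(K+S)` per unit active
  biomass; the half-saturation `K` is tiny relative to typical
  concentrations, so uptake is effectively on/off and the dynamics
  develop a sharp corner at nutrient exhaustion. This is what makes the
  system stiff.
* **Logistic crowding.** The active fraction cannot exceed the non-water
  volume `1 - eps_a`; growth of `f` carries the factor
  `(1 - f/(1-eps_a))`. The companion inactive fraction is never
  integrated — it is reported as `1 - eps_a - f`, so the algebraic
  closure is exact by construction.
* **Fickian supply, fixed sublayer.** Flux across the sublayer is
  proportional to `S_a - S` with constant `D` and `L_a`; there is no
  EPS-mediated transport and no osmotic spreading.

Two consequences of the structure are implemented as closed forms and
used throughout the tests as oracles:

* the **nutrient-equivalent mass** `S_a*V_a + S*sigma*L +
  rho*sigma*(1-eps_a)*L/Y` (`conserved_nutrient_mass()`) is an exact
  first integral — diffusion only moves nutrient between pools and
  consumption converts it to biomass at yield `Y`. Its numerical drift is
  the package's primary accuracy diagnostic.
* with `S >> K` the `f`-equation decouples into a logistic equation with
  equilibrium `(1-eps_a)*(1 - b/(Y*V_T))`
  (`quasi_steady_active_fraction()`), an analytic ceiling for the
  simulated activity peak; and full exhaustion pins the asymptotic
  thickness at `predicted_final_thickness()`, independent of every
  kinetic constant.

## Parameters

The defaults of `biofilm_params()` and `biofilm_state()` describe a
*B. subtilis* colony freshly spotted on an MSgg plate. Units are fixed to
cm / mg / day package-wide; no conversion layer exists because the whole
parameterisation lives in one unit system.

| name | default | units | meaning |
|---|---|---|---|
| `K` | 1e-4 | mg/cm³ | Monod half-saturation; effectively on/off uptake |
| `V_T` | 12.96 | mg/mg/day | maximum specific uptake rate |
| `Y` | 0.5 | mg/mg | biomass yield per nutrient consumed |
| `b` | 0.25 | /day | active-to-inactive conversion rate |
| `D` | 0.864 | cm²/day | diffusion coefficient across the sublayer |
| `sigma` | 1 | cm² | film–agar interface area |
| `eps_a` | 0.8 | — | water volume fraction of the film |
| `rho` | 300 | mg/cm³ | biomass density |
| `V_a` | 0.5 | cm³ | agar reservoir volume |
| `L_a` | 0.3 | cm | laminar sublayer thickness |

Initial condition: `L = 1e-4` cm (a monolayer-scale inoculum), `f = 0.15`,
`S = 4e-5` mg/cm³, `S_a = 15` mg/cm³ (the reservoir holds 7.5 mg, which at
yield 0.5 and density 300 converts to the 0.0626 cm thickness ceiling).

One typographic ambiguity in the source material for the `f`-balance was
resolved by re-deriving it: dividing the active-biomass mass balance
`d(rho*sigma*L*f)/dt` by `rho*sigma*L` forces the growth term to carry the
factor `f`, and the reduced system used here is the one consistent with
that derivation. The growth-dilution term `S*Y*f/(1-eps_a)*V_T*mu` inside
`dS/dt` — the effect of the rising upper boundary on the average in-film
concentration — is numerically tiny but kept, because dropping it would
break exact mass conservation, which the package uses as its accuracy
diagnostic.

## Numerical choices

* **Solver.** `deSolve`'s `lsoda`, which switches to a BDF method on
  stiffness. Defaults: `rtol = 1e-8`, per-variable `atol` of `1e-12` for
  `f` and `L` and `1e-10` for the concentrations, reflecting the four
  orders of magnitude between `L(0) = 1e-4` and `S_a(0) = 15`. Under
  these settings the conserved-mass drift on the reference scenario is a
  few parts in 10⁹, and the zero-nutrient limit (where `f(t) =
  f(0)e^{-bt}` exactly and `L` is constant) is reproduced to better than
  10⁻⁶ relative.
* **Clipping.** Monod kinetics is undefined for negative concentrations
  and a stiff solver can overshoot near exhaustion, so the kinetic terms
  floor `S` and `S_a` at zero inside the right-hand side, and saved
  states are clipped to non-negative concentrations with the count
  flagged on the result (`n_clipped`).
* **Trajectory grid and event refinement.** Runs save 2001 equally
  spaced states (the `n_out` setting). Event detection never reads the
  grid directly: the peak of `f` is located by continuous maximisation
  of a cubic interpolant, crossings by root finding on it, and the
  steady-state criterion evaluates the model's own `dL/dt` at the saved
  states before interpolating. Halving or doubling the grid moves
  detected event times by far less than 1%.
* **Operational event definitions.** "Depleted" means `S_a` below a
  fraction (default 1%) of its initial value — the reservoir only
  asymptotes to zero, so an exact-zero crossing never occurs, and the
  detected time is necessarily threshold-sensitive because the late
  decline is exponential. "Steady state" means the relative growth rate
  `(dL/dt)/L` below `1e-4`/day, a scale-free criterion insensitive to
  units. Both thresholds are arguments, not constants.
* **Horizons.** 10 days suffices for thickness and reservoir reporting
  (the steady-state event lands near day 3); activity reporting uses 30
  days so the post-exhaustion decay of `f` toward zero is visible.
  These sizes keep a full run under half a second.

## Parameter sweeps

`run_sweep()` varies one of `Y`, `V_T`, `D`, `rho`, `b` with everything
else held at the preset, one full integration plus event detection per
value; per-value failures are recorded in the result rather than aborting
the sweep. Sweep values default to `{0.5, 1, 2}` times the preset — wide
enough to exhibit every qualitative direction without committing to any
particular experimental grid. "Final thickness" is read at the
steady-state event, falling back to the end-of-span value with a warning
when a slow parameterisation has not converged within the horizon.

The comparative directions the suite asserts: final thickness rises with
`Y` and falls with `rho` (both finals agree with the conservation closed
form value by value); depletion time falls with `D` while the finals
across a `D`-sweep agree within 5% (conservation makes the limit
`D`-independent; the residual spread is a finite-horizon effect); the
activity peak falls with `b` and rises with `V_T`; and the late-time
activity falls with `V_T`, since faster uptake exhausts the reservoir
sooner and starts the decline earlier.

One direction needs care: the *final* thickness is fixed by mass
conservation and is therefore exactly independent of `V_T` — sweep
readouts differ only at solver-noise level (~10⁻¹⁰). The statement that
faster uptake gives a thicker film is a statement about the growth
transient, and that is how the package tests it: thickness at day 1,
mid-transient for all tested values, is strictly increasing in `V_T`.

## The calibration module and its synthetic data

Top-view transmission imaging measures optical density
`OD = -log10(I/I0)`; under the Beer–Lambert law this is proportional to
the material thickness, `OD = h / lambda`. The attenuation length
`lambda` is written here with units of length — it is the thickness that
produces one unit of OD — which fixes the dimensionally consistent
reading `h = OD * lambda` (the product form `OD = h*lambda` that
sometimes appears in print is a units slip; either reading differs only
by where the constant sits and leads to identical heights after
fitting). `fit_attenuation_length()` estimates `lambda` by least squares
through the origin — no intercept, because zero OD must mean zero height
— with the closed-form solution `sum(od*h)/sum(od^2)`. A single
informative point already determines `lambda`; only an all-zero OD
profile is rejected as unidentifiable.

`synthesize_profile()` generates the paired data this fit needs: a known
1-D height field (flat slab, dome, or a plateau with a raised rim — the
"coffee ring" left when the inoculation drop dries at its perimeter) is
pushed through the forward model `I = I0 * 10^(-h/lambda)`, optionally
degraded with multiplicative log-normal intensity noise, and stored
together with the ground truth. Profiles are one-dimensional, emulating
transmission averaged across the narrow direction of a cut slab. What the
generator does **not** emulate: spatially correlated illumination
gradients, detector saturation, scattering (which makes real attenuation
mildly nonlinear in thickness), or registration error between the
top-view and side-view images. Recovery tests on this generator therefore
demonstrate correctness of the estimator under its own model — exact
recovery without noise, a few-percent error at 5% intensity noise with
200 points — not robustness to every artefact of real microscopy.

## Known limitations

* No spatial resolution, so nothing the model says can be compared with
  radial profiles, ring patterns, or wrinkling.
* Nutrient transport is diffusion-only with a constant coefficient;
  EPS-driven transport and osmotic spreading are outside scope.
* The inactive fraction is inert: no lysis, no recycling of inactive
  biomass back to nutrient.
* Depletion timing is an operational quantity: it moves with the chosen
  threshold (steeply exponential tail), so comparisons across studies
  must fix the threshold first.
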