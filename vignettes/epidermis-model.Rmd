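---
title: "An agent-based epidermis on a deformable dermis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based epidermis on a deformable dermis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`epidermsim` simulates a patch of interfollicular epidermis as three coupled
particle systems in a laterally periodic box, open at the top:

* **Dermis** — a slab of mutually adhesive particles on a close-packed
  lattice (four layers by default; the deepest layer is immobile and anchors
  the tissue). The dermis has no imposed shape: it deforms under the forces
  transmitted through the basement membrane. Its stiffness is controlled by
  a single multiplier on the dermal-dermal adhesion strength.
* **Basement membrane** — a triangulated elastic sheet: harmonic springs on
  the lattice edges (stretching) and a `k_bend (1 - cos θ)` energy on every
  hinge, θ being the dihedral deviation from flat. The membrane adheres to
  the dermal particles below through the same pairwise potential.
* **Cells** — spheroids with equatorial/polar semi-axes `(a, c)` satisfying
  `a²c = R³` (volume conservation). Contact between spheroids uses an
  *effective separation* in which the vertical component is rescaled by the
  mean equatorial-to-polar ratio, so flattened cells stack tightly while
  keeping their lateral footprint.

All dynamics are overdamped (`ẋ = F`, damping 1) and integrated with
explicit Euler at `dt` below the stability bound `1/(4 k_max)`. The pairwise
potential is piecewise quadratic: linear repulsion below the rest
separation, an adhesion well that vanishes at the cutoff. Forces are exact
negative gradients of a total energy, so pure mechanical relaxation descends
that energy — one of the standing test invariants.

### Lifecycle

Basal cells are **stem** or **transit-amplifying (TA)**. Both are bound to
the membrane by a pull-only spring to the nearest membrane particle — stem
cells strongly (`k_stem`), TA cells weakly (`k_TA`); this differential
adhesion is what ultimately places stem cells on the tips of dermal
protrusions. Cells cycle stochastically: the waiting time is
`T_div · X` with `X` lognormal, mean 1, CV `cycle_cv`. Stem divisions are
asymmetric (stem + fresh TA with a budget of `N_div` divisions); TA
divisions are symmetric with the budget decremented. Division is possible
only while attached; crowding from repeated division pushes TA cells off
the membrane, and a TA cell carried beyond the detachment distance
delaminates irreversibly: it becomes spinous and its differentiation state
`w` starts growing.

### Differentiation, calcium and the second stimulant

`w` grows at `alpha (1 + beta_Ca·Ca + beta_S·S)` per day. Two fields live on
the cell-neighbour graph (graph-Laplacian exchange, linear decay):

* **Calcium** is injected as a fixed dose `Q_Ca` when a cell cornifies,
  split equally among its living suprabasal (spinous/granular) neighbours.
  With `lambda_Ca` of order one per day it stays a *localised* layer just
  beneath the cornified layer.
* **Stimulant** is secreted continuously by cornified cells onto their
  graph neighbours and decays more slowly (`lambda_S < lambda_Ca`), so it
  reaches deeper into the spinous layer.

The two factors set two boundaries: the stimulant paces the
spinous-to-granular transition (`w = w1`), and the calcium pulses
concentrated near the cornified boundary pace the granular-to-cornified
transition (`w = w2`). Cell type is a pure function of `w` with half-open
intervals; the first crossing of `w2` is the cornification event: it stamps
the time, arms the corneodesmosome integrity `D = 1`, releases the calcium
dose and transfers the cell's internal lipid store.

A deliberate design point is that the **baseline speed `alpha` is small
relative to the field-driven acceleration** (the accelerated rate is
roughly 4-6x baseline in homeostasis). Differentiation timing is then
governed by where a cell sits relative to recent cornification events.
This is what makes the reduced-supply regime degrade realistically: when
the cell supply is low the living suprabasal layer is thin and cornification
events are sparse, so cells in quiet neighbourhoods linger as isolated
granular stragglers (raising the dispersion `G`), while cells near an
event cascade receive concentrated doses (few living neighbours share each
dose) and race through the granular band.

### Lipids and desquamation

Granular cells produce internal lipid at `p_lip` per day, capped at
`L_max`; the store is released in one shot when the cell's calcium rises
above a threshold set just below the typical per-neighbour cornification
dose — so release *typically* happens when a neighbour cornifies, which is
the usual situation inside an intact granular layer. Release is purely
calcium-triggered: a cell that cornifies in an event-sparse neighbourhood
(the signature of reduced cell supply) never receives the trigger and
stays lipid-deficient (released lipid below 50% of the maximum); the count
of such cells is one of the layer-quality measures.

Cornified cells' junction integrity decays as `D ← D·exp(-dt/tau_desq)`;
a cornified cell desquamates (is removed) once `D < D_th` **and** it is
surface-exposed (no cell centre above it within one equatorial radius).
In homeostasis the cornified column is a first-in-first-out queue, so the
mean cornification-to-removal lag is close to `tau_desq · ln(1/D_th)` plus
a small exposure-queueing delay.

## Units and calibration

Lengths are micrometres, times days. Two printed anchors fix the scales:

1. the undifferentiated cell diameter is 10 µm (`R = 5`), which is also the
   equilibrium separation of two undifferentiated cells under the default
   potential (`r_eq = a_i + a_j`);
2. the mean lag between cornification and desquamation is 14 days.

`tau_desq` is the calibrated parameter behind anchor 2:
`calibrate_desquamation()` bisects it against a homeostasis run (the lag is
monotone in `tau_desq`). The shipped default, `tau_desq = 5.5`, is the
output of that procedure; it sits a little below the naive
`14/ln(1/D_th) ≈ 6.08` because surface-exposure queueing adds roughly a day.
The remaining free rates (`alpha`, the `beta`s, field rates, `d_detach`)
were set once so that the whole-epidermis turnover — basal residence plus
suprabasal transit plus the 14-day cornified lag — comes out near 28 days
in the homeostasis regime `(N_div, T_div) = (14, 4.0)`, with the layer
phenomenology described above. They are deliberately not regime-dependent:
the reduced-supply regime `(8, 4.4)`, the stiffened dermis and the corn all
run with the same constants.

Parameter defaults worth knowing (all in `default_params()`):

| parameter | default | meaning |
|---|---|---|
| `N_div`, `T_div` | 14, 4.0 d | TA division budget and period |
| `cycle_cv` | 0.2 | lognormal cell-cycle jitter |
| `w1`, `w2` | 1, 2 | differentiation thresholds |
| `alpha` | 0.05 /d | baseline differentiation speed |
| `beta_Ca`, `beta_S` | 5, 4 | field acceleration coefficients |
| `lambda_Ca`, `lambda_S` | 0.8, 0.25 /d | field decay (calcium local, stimulant long-ranged) |
| `Q_Ca`, `s_rate` | 3, 0.12 /d | cornification dose, cornified secretion |
| `p_lip`, `L_max` | 0.3 /d, 1 | lipid production and cap |
| `tau_desq`, `D_th` | 5.5 d, 0.1 | corneodesmosome decay and removal threshold |
| `q_min` | 0.25 | terminal aspect ratio of cornified cells |
| `d_detach` | 3 µm | TA detachment distance beyond contact |
| `dt` | 0.008 d | Euler step (stability bound 0.01) |

A note on the mechanical constants: the membrane-dermis adhesion
(`k_adh_mem`) is deliberately much stronger than the dermal-dermal
cohesion, so the membrane cannot peel off the dermis and wrinkle on its
own — any vertical structure it develops has to deform the dermis with it.
This is what routes the dermal stiffness into the epidermis: protrusions
form only where the dermis yields, so multiplying the dermal cohesion
(`stiffness_mult = 4`) suppresses the membrane deformation amplitude and,
through the lost surface area, the basal cell supply. With a weak coupling
the membrane buckles regardless of the dermis and the stiffness multiplier
has no observable effect.

## What the simulations emulate — and what they do not

The initial condition is a cold start: flat dermis, flat membrane at rest,
a synchronised-but-jittered basal monolayer, no suprabasal cells, zero
fields. Everything above the basal layer is *emergent*: stratification,
dermal protrusions with stem cells on top (a buckling instability driven by
division pressure plus differential adhesion), the localised calcium layer,
the cornified queue. A run therefore needs a burn-in of about two turnovers
(~56 days) before statistics are stationary; all regime comparisons in the
tests time-average after that transient.

Desk-scale defaults (150-300 µm boxes, a few hundred basal cells) are far
smaller than real skin and smaller than a full-scale run of this model
class; absolute layer thicknesses fluctuate accordingly, which is why the
test surface is *orderings and calibrated anchors*, not absolute heat-map
values. The model has no histology: no nuclei (so parakeratosis is out of
reach), no explicit water loss (structure and lipid content are the barrier
proxies), no single-progenitor variant, no continuum calcium, no inertia.

## Numerical choices and degenerate inputs

* Neighbour search uses a uniform grid at the largest interaction cutoff;
  results are identical to the naive O(n²) loop (tested to 1e-10). Domains
  too small for three grid bins fall back to the naive loop.
* The metric grid uses half-open tiles, so each cell lands in exactly one
  tile. Empty tiles contribute `H_ij = 0` to the thickness mean and the
  spatial variation but are excluded from the dispersion mean (`G_ij` needs
  extremes); this convention is declared, not derivable.
* `G_ij = -H_ij` for a single-cell tile (forced by the definition).
* A cornification with no living suprabasal neighbour discards its calcium
  dose with a warning (counted in the event log) rather than inventing a
  recipient.
* Coincident particles and degenerate (zero-area) membrane triangles are
  hard errors, as are non-finite positions after a step and `dt` above the
  stability bound.
* Ties in desquamation exposure are broken conservatively: any cell centre
  strictly above within one equatorial radius blocks removal.
* The corn lesion footprint is the convex hull of the abnormal-lineage
  basal cells; intrusion depth compares the cornified layer's lower
  boundary inside that footprint against the non-lesional mean on a 25 µm
  tile grid.

## Worked example

```{r}
library(epidermsim)
sc <- scenario_params("fixture_small", seed = 101, days = 170)
res <- run_scenario(sc, sample_every = 0.5)
res$summary$turnover
time_average(res$metrics, burn_in = 56)
```

A 170-day fixture run (two turnovers of burn-in, four of measurement)
reproduces the two calibration anchors from the event log alone:
birth-to-shedding near 28 days and cornification-to-shedding near 14 days.
`scripts/acceptance.R` is exactly this computation.

## Known limitations

* The exposure rule makes the desquamation lag weakly dependent on the
  surface roughness; `tau_desq` absorbs that in calibration.
* At very small domains (under ~100 µm) a single stem niche dominates and
  regime orderings become noisy; comparisons should use 150 µm boxes or
  larger and several seeds.
* The explicit Euler integrator is first-order; `dt` is two-thirds of the
  stability bound by default, and halving it changes the reported
  statistics well within their seed-to-seed spread.
* Stochastic realisations are reproducible only through the R RNG stream:
  identical seeds give bit-identical runs, but any change to the order of
  random draws (e.g. a different division batch order) is a behavioural
  change even if the physics is unchanged.
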