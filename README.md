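# epidermsim

A three-dimensional agent-based model of the epidermis on a **deformable
dermis**, for computational skin biology: studying how the cell supply from
the basal layer, the mechanics of the dermis and calcium-driven
differentiation together maintain (or destroy) the stratified layer
structure that provides the skin barrier.

The tissue is three coupled particle systems in a laterally periodic box:

* a **dermis** of mutually adhesive particles (stiffness = adhesion
  strength × `stiffness_mult`), deepest layer anchored;
* a **basement membrane**: a triangulated sheet with stretching energy
  `Σ ½ k_s (l − l₀)²` and bending energy `Σ k_b (1 − cos θ)`, adhesive to
  the dermis;
* **keratinocytes** as volume-conserving spheroids (`a²c = R³`) that
  divide while attached to the membrane (stem cells indefinitely, TA cells
  at most `N_div` times, stochastic period `T_div`), delaminate under
  crowding, differentiate (spinous → granular → cornified as the state
  variable `w` crosses `w₁`, `w₂`), flatten, produce and release lipids,
  and desquamate when their corneodesmosome integrity
  `D(t) = e^{−(t−t_corn)/τ_desq}` falls below a threshold while
  surface-exposed.

Differentiation speed is `α (1 + β_Ca·Ca + β_S·S)`: calcium is released as
a localized pulse when a neighbour cornifies, the second stimulant is
secreted continuously by cornified cells and reaches deeper; the two
fields set the two layer boundaries. Layer quality is scored on an
`M₁ × M₂` subregion grid by the mean thickness `H`, the vertical dispersion
`G = z_max − z_min − H` and the spatial variation `E = sd(H_ij)`, plus
lipid statistics, basal-layer diagnostics and the membrane deformation
amplitude. The length/time scales are calibrated so the cell diameter is
10 µm, the cornification→shedding lag is 14 days, and the whole-epidermis
turnover is ≈ 28 days.

## Worked example

```r
library(epidermsim)

sc  <- scenario_params("fixture_small", seed = 101, days = 170)
res <- run_scenario(sc, sample_every = 0.5)

res$summary$turnover
#> $turnover   28.4   # days, basal birth -> desquamation
#> $corn_lag   14.3   # days, cornification -> desquamation
#> $n_turnover 3173
#> $n_lag      3173

round(time_average(res$metrics, burn_in = 56), 2)
#>  H_gran  G_gran  E_gran  H_corn  G_corn  E_corn lipid_ratio n_deficient
#>    2.35    7.40    0.58   13.18   29.31    0.99        0.87        1.78
#> div_per_day n_basal n_proliferative mem_amplitude n_cells
#>       32.9   258.9           167.5          8.22  1044.8
```

(Numbers from the run above; stochastic, so other seeds move them a few
percent.) A flat start self-organises into basal / spinous / granular /
cornified layers on a dermis that buckles into upward protrusions with the
strongly-adhering stem cells on their tips; cornified cells queue for
about 14 days before shedding, giving the ~28-day turnover. Presets:
`homeostasis` (N_div = 14, T_div = 4.0), `reduced_supply` (8, 4.4 — thin,
ragged, lipid-deficient layers), `stiff_dermis` (4× dermal adhesion —
flattened membrane, reduced supply), `corn` (one hyperproliferative,
fast-differentiating stem lineage → cornified intrusion pressing the
dermis down; see `run_corn()` / `corn_report()`), and the desk-scale
`fixture_small`.

Other entry points: `run_sweep()` (supply-plane heat maps),
`calibrate_desquamation()` (bisection of `τ_desq` against the 14-day
anchor), `write_state_json()`/`read_state_json()` (lossless snapshots,
resumable), `write_vtk()` (visualisation export), and a thin CLI at
`inst/cli/epidermsim`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the scaled-down homeostasis fixture (two 28-day turnovers of burn-in,
then four of measurement) and recomputes from the event log the two
calibration anchors: `t1`, the mean time from a cell's creation by basal
division to its removal by desquamation, and `t2`, the mean lag between
cornification and removal (both in days, with the number of shed cells
behind each).
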